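#' Construct a site-by-second detection matrix
#'
#' Holds the channel-wise per-second classifier output for a recording:
#' seizure probabilities and thresholded binary verdicts for each of the 21
#' montage sites at each whole second.
#'
#' @param probabilities Numeric sites x seconds matrix in [0, 1].
#' @param site_names Character vector of site names (rows).
#' @param threshold Decision threshold; a cell is flagged when its
#'   probability is greater than or equal to the threshold.
#' @param verdicts Optional integer matrix; recomputed from `probabilities`
#'   and `threshold` when omitted, and checked for consistency when given.
#' @return An object of class `detection_matrix`.
#' @export
detection_matrix <- function(probabilities, site_names, threshold = 0.5,
                             verdicts = NULL) {
  probabilities <- as.matrix(probabilities)
  assert_that(nrow(probabilities) == length(site_names),
              "one row of probabilities per site is required")
  assert_that(all(is.finite(probabilities)) &&
                all(probabilities >= 0 & probabilities <= 1),
              "probabilities must lie in [0, 1]")
  expected <- matrix(as.integer(probabilities >= threshold),
                     nrow = nrow(probabilities))
  if (is.null(verdicts)) {
    verdicts <- expected
  } else {
    verdicts <- matrix(as.integer(as.matrix(verdicts)), nrow = nrow(expected))
    assert_that(identical(verdicts, expected),
                "verdicts inconsistent with probabilities and threshold")
  }
  dimnames(probabilities) <- list(site_names, NULL)
  dimnames(verdicts) <- list(site_names, NULL)
  structure(
    list(
      site_names = as.character(site_names),
      seconds = ncol(probabilities),
      probabilities = probabilities,
      verdicts = verdicts,
      threshold = threshold
    ),
    class = "detection_matrix"
  )
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf("<detection_matrix> %d sites x %d seconds, threshold %g\n",
              length(x$site_names), x$seconds, x$threshold))
  cat(sprintf("flagged cells: %d / %d\n", sum(x$verdicts),
              length(x$verdicts)))
  invisible(x)
}

#' Tidy a detection matrix into a long tibble
#'
#' @param x A [detection_matrix()].
#' @param ... Unused.
#' @return Tibble with columns `site`, `second` (1-based), `probability`,
#'   `flagged`.
#' @method tidy detection_matrix
#' @export
tidy.detection_matrix <- function(x, ...) {
  tibble::tibble(
    site = rep(x$site_names, times = x$seconds),
    second = rep(seq_len(x$seconds), each = length(x$site_names)),
    probability = as.vector(x$probabilities),
    flagged = as.integer(as.vector(x$verdicts))
  )
}

#' Write a detection matrix to JSON
#'
#' Lossless round-trip of sites, threshold, probabilities and verdicts.
#' Probabilities outside [0, 1] are rejected at construction time.
#'
#' @param matrix A [detection_matrix()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_detection_matrix <- function(matrix, path) {
  assert_that(inherits(matrix, "detection_matrix"),
              "`matrix` must be a detection_matrix")
  payload <- list(
    site_names = matrix$site_names,
    seconds = matrix$seconds,
    threshold = matrix$threshold,
    probabilities = apply(matrix$probabilities, 1, identity, simplify = FALSE)
  )
  payload$probabilities <- lapply(seq_along(matrix$site_names), function(i) {
    as.vector(matrix$probabilities[i, ])
  })
  names(payload$probabilities) <- matrix$site_names
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a detection matrix from JSON
#'
#' @param path Path written by [write_detection_matrix()].
#' @return A [detection_matrix()].
#' @export
read_detection_matrix <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  probs <- do.call(rbind, payload$probabilities)
  detection_matrix(probs, names(payload$probabilities),
                   threshold = payload$threshold)
}
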