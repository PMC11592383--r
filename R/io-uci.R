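#' Read a labeled single-channel window table (UCI layout)
#'
#' Reads a CSV of one-second single-channel EEG windows: 178 sample columns
#' followed by an integer class label column `y` in 1..5. An optional unnamed
#' leading row-ID column (as present in the public mirror of the dataset) is
#' tolerated and dropped. Malformed tables (wrong column count, non-integer
#' or out-of-range labels) are rejected.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `x1`..`x178` and integer `y`.
#' @export
read_uci_table <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) == 180) {
    first <- df[[1]]
    id_like <- names(df)[1] %in% c("", "X", "Unnamed: 0", "id", "ID") ||
      is.character(first)
    assert_that(id_like,
                "expected 179 data columns (178 samples + label), got 180 without a recognizable row-ID column")
    df <- df[, -1, drop = FALSE]
  }
  assert_that(ncol(df) == 179,
              paste0("expected 179 data columns (178 samples + label), got ",
                     ncol(df)))
  y_raw <- df[[179]]
  y_num <- suppressWarnings(as.numeric(y_raw))
  assert_that(!anyNA(y_num) && all(y_num == floor(y_num)),
              "label column must be integer-valued")
  assert_that(all(y_num >= 1 & y_num <= 5),
              "labels must lie in 1..5")
  x <- df[, 1:178, drop = FALSE]
  bad <- !vapply(x, is.numeric, logical(1))
  if (any(bad)) {
    x[bad] <- lapply(x[bad], function(col) {
      v <- suppressWarnings(as.numeric(col))
      assert_that(!anyNA(v), "non-numeric sample value in table")
      v
    })
  }
  out <- tibble::as_tibble(x, .name_repair = "minimal")
  names(out) <- paste0("x", 1:178)
  out$y <- as.integer(y_num)
  out
}

#' Write a labeled window table as UCI-layout CSV
#'
#' @param windows Tibble/data frame with 178 sample columns and a final
#'   integer label column `y`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_uci_table <- function(windows, path) {
  assert_that(ncol(windows) == 179, "table must have 178 sample columns plus `y`")
  assert_that("y" %in% names(windows), "label column must be named `y`")
  assert_that(all(windows$y %in% 1:5), "labels must lie in 1..5")
  utils::write.csv(windows, path, row.names = FALSE)
  invisible(path)
}

# Extract the 178-column sample matrix from a window-set tibble.
window_matrix <- function(windows) {
  cols <- grep("^x[0-9]+$", names(windows), value = TRUE)
  m <- as.matrix(windows[, cols, drop = FALSE])
  dimnames(m) <- NULL
  m
}
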