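#' Onset second and onset sites of a detected seizure
#'
#' The onset second is the first second with at least one flagged site; the
#' onset site set is the union of flagged sites within the following
#' `onset_window_s` seconds, capturing the sites involved as the seizure
#' establishes itself.
#'
#' @param matrix A [detection_matrix()].
#' @param onset_window_s Window length in seconds (default 5).
#' @return List with `onset_second` (1-based) and `sites` (character).
#' @export
onset_sites <- function(matrix, onset_window_s = 5) {
  assert_that(inherits(matrix, "detection_matrix"),
              "`matrix` must be a detection_matrix")
  flagged_seconds <- which(colSums(matrix$verdicts) > 0)
  assert_that(length(flagged_seconds) > 0, "no seizure detected in matrix")
  t0 <- flagged_seconds[1]
  win <- t0:min(t0 + onset_window_s - 1, matrix$seconds)
  sites <- matrix$site_names[rowSums(matrix$verdicts[, win, drop = FALSE]) > 0]
  list(onset_second = t0, sites = sites)
}

#' Terminal sites of a detected seizure
#'
#' Sites still flagged near the end of the seizure: the union of flagged
#' sites within the `terminal_window_s` seconds ending at the last flagged
#' second.
#'
#' @inheritParams onset_sites
#' @param terminal_window_s Window length in seconds (default 5).
#' @return Character vector of site names.
#' @export
terminal_sites <- function(matrix, terminal_window_s = 5) {
  assert_that(inherits(matrix, "detection_matrix"),
              "`matrix` must be a detection_matrix")
  flagged_seconds <- which(colSums(matrix$verdicts) > 0)
  assert_that(length(flagged_seconds) > 0, "no seizure detected in matrix")
  t1 <- flagged_seconds[length(flagged_seconds)]
  win <- max(t1 - terminal_window_s + 1, 1):t1
  matrix$site_names[rowSums(matrix$verdicts[, win, drop = FALSE]) > 0]
}

lateral_hemispheres <- function(sites) {
  if (length(sites) == 0) return(character())
  h <- site_hemisphere(sites)
  unique(h[h != "midline"])
}

#' Hemisphere-level seizure-onset-zone verdict
#'
#' Midline sites (Fz, Cz, Pz) are ignored for lateralization. If the
#' lateralized onset sites span both hemispheres the verdict is
#' "both hemispheres". If onset is confined to one hemisphere, the verdict
#' is that hemisphere; terminal evidence refines but never overrides a
#' unilateral onset. Onset sets containing only midline sites are
#' indeterminate and raise an error.
#'
#' @param onset Character vector of onset site names (non-empty).
#' @param terminal Character vector of terminal site names.
#' @param layout Electrode layout (default [electrode_layout()]); present for
#'   interface completeness, hemisphere tags follow the 10-20 naming rule.
#' @return One of "left hemisphere", "right hemisphere", "both hemispheres".
#' @export
#' @examples
#' classify_soz(c("Pz", "C4", "P4", "F8", "T4"), c("F4", "F8"))
classify_soz <- function(onset, terminal = character(),
                         layout = electrode_layout()) {
  assert_that(length(onset) > 0, "onset site set must be non-empty")
  onset_h <- lateral_hemispheres(onset)
  assert_that(length(onset_h) > 0,
              "indeterminate laterality: onset contains only midline sites")
  if (length(onset_h) == 2) return("both hemispheres")
  paste(onset_h, "hemisphere")
}

#' Focal versus generalized seizure type
#'
#' A seizure whose lateralized onset sites are confined to one hemisphere
#' (possibly plus midline sites) is focal; onset activity in both
#' hemispheres is generalized.
#'
#' @inheritParams classify_soz
#' @return "focal" or "generalized".
#' @export
#' @examples
#' classify_seizure_type(c("O1", "O2", "T5", "T6", "P4"))  # generalized
classify_seizure_type <- function(onset, layout = electrode_layout()) {
  assert_that(length(onset) > 0, "onset site set must be non-empty")
  onset_h <- lateral_hemispheres(onset)
  assert_that(length(onset_h) > 0,
              "indeterminate laterality: onset contains only midline sites")
  if (length(onset_h) == 2) "generalized" else "focal"
}

#' Full seizure-onset-zone report for a detection matrix
#'
#' Extracts onset and terminal site sets, the hemisphere-level SOZ verdict
#' and the focal/generalized seizure type from a site-by-second detection
#' matrix.
#'
#' @param matrix A [detection_matrix()].
#' @param onset_window_s,terminal_window_s Window lengths in seconds.
#' @return An object of class `soz_report`.
#' @export
soz_report <- function(matrix, onset_window_s = 5, terminal_window_s = 5) {
  on <- onset_sites(matrix, onset_window_s)
  term <- terminal_sites(matrix, terminal_window_s)
  structure(
    list(onset_second = on$onset_second, onset_sites = on$sites,
         terminal_sites = term,
         soz_verdict = classify_soz(on$sites, term),
         seizure_type = classify_seizure_type(on$sites),
         onset_window_s = onset_window_s,
         terminal_window_s = terminal_window_s),
    class = "soz_report"
  )
}

#' @export
print.soz_report <- function(x, ...) {
  cat("<soz_report>\n")
  cat(sprintf("  onset second: %d\n", x$onset_second))
  cat(sprintf("  onset sites: %s\n", paste(x$onset_sites, collapse = ", ")))
  cat(sprintf("  terminal sites: %s\n", paste(x$terminal_sites, collapse = ", ")))
  cat(sprintf("  SOZ: %s\n", x$soz_verdict))
  cat(sprintf("  seizure type: %s\n", x$seizure_type))
  invisible(x)
}

#' Tidy a SOZ report into a site table
#' @param x A `soz_report`.
#' @param ... Unused.
#' @return Tibble with one row per site appearing in the onset or terminal
#'   set: `site`, `hemisphere`, `in_onset`, `in_terminal`.
#' @method tidy soz_report
#' @export
tidy.soz_report <- function(x, ...) {
  sites <- union(x$onset_sites, x$terminal_sites)
  tibble::tibble(
    site = sites,
    hemisphere = site_hemisphere(sites),
    in_onset = sites %in% x$onset_sites,
    in_terminal = sites %in% x$terminal_sites
  )
}

#' One-row summary of a SOZ report
#' @param x A `soz_report`.
#' @param ... Unused.
#' @return One-row tibble with the verdicts and set sizes.
#' @method glance soz_report
#' @export
glance.soz_report <- function(x, ...) {
  tibble::tibble(
    onset_second = x$onset_second,
    n_onset_sites = length(x$onset_sites),
    n_terminal_sites = length(x$terminal_sites),
    soz_verdict = x$soz_verdict,
    seizure_type = x$seizure_type
  )
}

#' Write a SOZ report as JSON
#' @param report A `soz_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_soz_report <- function(report, path) {
  assert_that(inherits(report, "soz_report"), "`report` must be a soz_report")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- topographic rendering -------------------------------------------------

topomap_state <- function(matrix, seconds) {
  assert_that(inherits(matrix, "detection_matrix"),
              "`matrix` must be a detection_matrix")
  assert_that(all(seconds >= 1 & seconds <= matrix$seconds),
              "requested second out of matrix range")
  layout <- electrode_layout()
  dplyr::bind_rows(lapply(seconds, function(s) {
    tibble::tibble(
      second = s,
      site = matrix$site_names,
      flagged = as.integer(matrix$verdicts[, s])
    )
  })) |>
    dplyr::left_join(layout, by = "site")
}

head_disc <- function() {
  th <- seq(0, 2 * pi, length.out = 181)
  list(
    circle = tibble::tibble(x = cos(th), y = sin(th)),
    nose = tibble::tibble(x = c(-0.12, 0, 0.12), y = c(0.993, 1.12, 0.993))
  )
}

topomap_panel <- function(state) {
  hd <- head_disc()
  ggplot2::ggplot(state, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = hd$circle, linewidth = 0.4) +
    ggplot2::geom_path(data = hd$nose, linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(fill = factor(.data$flagged)),
                        shape = 21, size = 7, stroke = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$site), size = 2.3) +
    ggplot2::scale_fill_manual(values = c("0" = "white", "1" = "red"),
                               guide = "none") +
    ggplot2::coord_fixed(xlim = c(-1.25, 1.25), ylim = c(-1.15, 1.2)) +
    ggplot2::facet_wrap(~second, labeller = ggplot2::labeller(
      second = function(s) paste0("T = ", s, " s"))) +
    ggplot2::theme_void() +
    ggplot2::theme(strip.text = ggplot2::element_text(size = 10))
}

#' Render seizure-site topographic maps
#'
#' Draws the 10-20 head-disc map for each requested second, flagged sites
#' in red, plus a multi-panel sequence figure showing the spread of the
#' seizure over those seconds.
#'
#' @param matrix A [detection_matrix()].
#' @param seconds Integer vector of 1-based seconds to render (must lie
#'   within the matrix range).
#' @param path Optional output directory; if given, one PNG per second
#'   (`topomap_T<second>.png`) and a `topomap_sequence.png` are written.
#' @return Invisibly, a list with `plots` (one ggplot per second),
#'   `sequence` (multi-panel ggplot) and `states` (tibble of per-second
#'   site render states).
#' @export
render_topomap <- function(matrix, seconds, path = NULL) {
  states <- topomap_state(matrix, seconds)
  plots <- lapply(seconds, function(s) {
    topomap_panel(dplyr::filter(states, .data$second == s))
  })
  names(plots) <- paste0("T", seconds)
  sequence <- topomap_panel(states)
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(seconds)) {
      ggplot2::ggsave(file.path(path, sprintf("topomap_T%d.png", seconds[i])),
                      plots[[i]], width = 4, height = 4, dpi = 120)
    }
    ggplot2::ggsave(file.path(path, "topomap_sequence.png"), sequence,
                    width = 2.8 * min(length(seconds), 5),
                    height = 2.8 * ceiling(length(seconds) / 5), dpi = 120)
  }
  invisible(list(plots = plots, sequence = sequence, states = states))
}

#' Topographic sequence plot of a detection matrix
#'
#' Renders five evenly spaced seconds spanning the detected seizure (or the
#' whole recording when nothing is flagged).
#'
#' @param object A [detection_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot detection_matrix
#' @export
autoplot.detection_matrix <- function(object, ...) {
  flagged <- which(colSums(object$verdicts) > 0)
  span <- if (length(flagged) > 0) range(flagged) else c(1, object$seconds)
  secs <- unique(round(seq(span[1], span[2], length.out = min(5, diff(span) + 1))))
  topomap_panel(topomap_state(object, secs))
}

#' Onset-sites topographic plot of a SOZ report
#'
#' @param object A `soz_report`.
#' @param ... Unused.
#' @return A ggplot object highlighting the onset sites.
#' @method autoplot soz_report
#' @export
autoplot.soz_report <- function(object, ...) {
  layout <- electrode_layout()
  state <- dplyr::mutate(
    layout,
    second = object$onset_second,
    flagged = as.integer(.data$site %in% object$onset_sites)
  )
  topomap_panel(state) +
    ggplot2::labs(title = paste0("Onset sites (", object$soz_verdict, ", ",
                                 object$seizure_type, " seizure)"))
}
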