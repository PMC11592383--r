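#' Channel-wise per-second seizure-site detection
#'
#' Applies the trained single-channel classifier to every montage channel of
#' a multi-channel recording: the 21 canonical channels are selected and
#' ordered, band-pass filtered, cut into non-overlapping 1-s windows,
#' resampled to the classifier's input length, standardized per window, and
#' classified. The identically trained model is applied to every channel
#' (training 21 copies of the same model on the same data with the same
#' procedure yields one weight set).
#'
#' @param recording An [eeg_recording()] containing (at least) the 21
#'   canonical montage channels; duration must be >= 1 s.
#' @param model A trained `seizure_cnn` (or checkpoint loaded with
#'   [load_checkpoint()]); carries the preprocessing configuration used at
#'   training time.
#' @return A [detection_matrix()]: 21 sites x whole seconds, probabilities
#'   and thresholded verdicts in canonical site order.
#' @export
detect_sites <- function(recording, model) {
  assert_that(inherits(model, "seizure_cnn"), "`model` must be a seizure_cnn")
  pp <- model$preprocess
  rec <- select_channels(recording)
  assert_that(ncol(rec$data) >= rec$sampling_rate * pp$window_seconds,
              "recording shorter than one analysis window")
  rec <- bandpass(rec, pp$band_low, pp$band_high)
  sites <- rec$channel_names
  probs <- NULL
  for (i in seq_along(sites)) {
    win <- segment(rec$data[i, ], rec$sampling_rate, pp$window_seconds)
    if (ncol(win) != pp$target_length) {
      win <- t(apply(win, 1, resample_window, target_length = pp$target_length))
    }
    win <- standardize_rows(win)
    p <- cnn_forward(model$weights, win)
    probs <- rbind(probs, p)
  }
  detection_matrix(probs, sites, threshold = model$spec$threshold)
}

#' Marginal flagged-cell counts of a detection matrix
#'
#' @param matrix A [detection_matrix()].
#' @return List with `per_second` (tibble: `second`, `n_sites`) and
#'   `per_site` (tibble: `site`, `n_seconds`).
#' @export
summarize_counts <- function(matrix) {
  assert_that(inherits(matrix, "detection_matrix"),
              "`matrix` must be a detection_matrix")
  list(
    per_second = tibble::tibble(second = seq_len(matrix$seconds),
                                n_sites = as.integer(colSums(matrix$verdicts))),
    per_site = tibble::tibble(site = matrix$site_names,
                              n_seconds = as.integer(rowSums(matrix$verdicts)))
  )
}
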