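#' Construct a multi-channel EEG recording
#'
#' Lightweight container for multi-channel scalp EEG: a channels-by-samples
#' numeric matrix in microvolts, ordered channel names, a single sampling
#' rate, and optional seizure annotations.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param channel_names Character vector, one name per row of `data`.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param annotations Optional data frame with columns `start`, `end`
#'   (seconds from recording start) and `label`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_names, sampling_rate, annotations = NULL) {
  data <- as.matrix(data)
  assert_that(is.numeric(data), "`data` must be a numeric matrix")
  assert_that(length(channel_names) == nrow(data),
              "`channel_names` length must equal the number of data rows")
  assert_that(is.numeric(sampling_rate) && length(sampling_rate) == 1 &&
                sampling_rate > 0, "`sampling_rate` must be a positive scalar")
  if (!is.null(annotations)) {
    annotations <- tibble::as_tibble(annotations)
    assert_that(all(c("start", "end") %in% names(annotations)),
                "`annotations` needs `start` and `end` columns")
  }
  rownames(data) <- channel_names
  structure(
    list(
      channel_names = as.character(channel_names),
      sampling_rate = as.numeric(sampling_rate),
      data = data,
      annotations = annotations
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$data) / x$sampling_rate
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, dur))
  cat("channels:", paste(x$channel_names, collapse = " "), "\n")
  if (!is.null(x$annotations) && nrow(x$annotations) > 0) {
    cat(sprintf("annotations: %d interval(s)\n", nrow(x$annotations)))
  }
  invisible(x)
}

#' Duration of a recording in whole seconds
#' @param recording An `eeg_recording`.
#' @return Integer count of whole seconds.
#' @export
recording_seconds <- function(recording) {
  as.integer(floor(ncol(recording$data) / recording$sampling_rate))
}

#' Tidy a recording into a long tibble
#'
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @return Tibble with columns `site`, `time` (s), `value` (microvolts).
#' @method tidy eeg_recording
#' @export
tidy.eeg_recording <- function(x, ...) {
  n <- ncol(x$data)
  tibble::tibble(
    site = rep(x$channel_names, each = n),
    time = rep((seq_len(n) - 1) / x$sampling_rate, times = nrow(x$data)),
    value = as.vector(t(x$data))
  )
}
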