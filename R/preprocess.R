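#' Band-pass filter a recording
#'
#' Applies a 4th-order Butterworth band-pass (default 0.53-40 Hz, the band
#' carrying the information relevant to seizure detection) forward-backward
#' (zero-phase) to every channel. Zero-phase filtering avoids shifting spike
#' timing across the 1-s analysis windows.
#'
#' @param recording An [eeg_recording()].
#' @param low,high Band edges in Hz; `high` must be below the Nyquist rate.
#' @param order Butterworth order (per pass).
#' @return A filtered [eeg_recording()] of the same shape.
#' @export
bandpass <- function(recording, low = 0.53, high = 40, order = 4) {
  assert_that(inherits(recording, "eeg_recording"),
              "`recording` must be an eeg_recording")
  fs <- recording$sampling_rate
  assert_that(low > 0 && high > low, "band edges must satisfy 0 < low < high")
  assert_that(high < fs / 2, "`high` must be below the Nyquist frequency")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  pad <- ceiling(2 * fs / max(low, 1e-6))  # covers the slow high-pass transient
  out <- recording
  out$data <- t(apply(recording$data, 1, function(x) {
    filtfilt_padded(bf, x, pad)
  }))
  rownames(out$data) <- recording$channel_names
  out
}

# Forward-backward filtering with odd-reflection end padding, so the filter
# sees a continuous signal and start/end transients stay out of the data.
filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  if (pad < 1) return(signal::filtfilt(bf, x))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(pad + 1):(pad + n)]
}

# Frequency response magnitude of the zero-phase band-pass at given
# frequencies (Hz); used to verify stopband/passband bounds.
bandpass_response <- function(freqs, fs, low = 0.53, high = 40, order = 4) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  w <- 2 * pi * freqs / fs
  z <- exp(1i * w)
  num <- vapply(z, function(zz) sum(bf$b * zz^-(seq_along(bf$b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(bf$a * zz^-(seq_along(bf$a) - 1)), complex(1))
  Mod(num / den)^2  # squared: filtfilt applies the filter twice
}

#' Select and order the 21 canonical montage channels
#'
#' Keeps exactly the 21 sites of the 10-20 montage (dropping T1/T2, ECG, EMG
#' and any other auxiliary channels) and orders them canonically. Channel
#' labels are normalized before matching, so EDF dialects such as
#' "EEG Fp1-Ref" are recognized.
#'
#' @param recording An [eeg_recording()].
#' @param sites Ordered site names to select (default [canonical_sites()]).
#' @return An [eeg_recording()] with exactly `length(sites)` channels in order.
#' @export
select_channels <- function(recording, sites = canonical_sites()) {
  assert_that(inherits(recording, "eeg_recording"),
              "`recording` must be an eeg_recording")
  norm <- normalize_channel_name(recording$channel_names)
  idx <- match(tolower(sites), tolower(norm))
  if (anyNA(idx)) {
    stop("missing channel(s): ", paste(sites[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  out <- recording
  out$data <- recording$data[idx, , drop = FALSE]
  out$channel_names <- sites
  rownames(out$data) <- sites
  out
}

#' Cut a signal into non-overlapping fixed-length windows
#'
#' Divides a single-channel signal into consecutive windows of
#' `window_seconds * sampling_rate` samples; the trailing partial window is
#' discarded.
#'
#' @param x Numeric signal vector.
#' @param sampling_rate Sampling rate in Hz.
#' @param window_seconds Window length in seconds (default 1).
#' @return A matrix, one window per row.
#' @export
#' @examples
#' nrow(segment(numeric(4097), sampling_rate = 178))  # 23 windows
segment <- function(x, sampling_rate, window_seconds = 1) {
  wlen <- as.integer(round(sampling_rate * window_seconds))
  assert_that(wlen >= 1, "window must contain at least one sample")
  assert_that(length(x) >= wlen,
              "signal shorter than one window")
  n_win <- floor(length(x) / wlen)
  matrix(x[seq_len(n_win * wlen)], nrow = n_win, ncol = wlen, byrow = TRUE)
}

#' Resample a window to an exact target length
#'
#' Polyphase rational resampling (with anti-aliasing) to exactly
#' `target_length` samples; e.g. a 1-s, 256-sample clinical window becomes
#' the 178-sample layout the classifier was trained on (ratio 89/128).
#' When the lengths already match the window is returned unchanged.
#'
#' @param window Numeric vector (length >= 2).
#' @param target_length Desired output length (default 178).
#' @return Numeric vector of length `target_length`.
#' @export
resample_window <- function(window, target_length = 178) {
  n <- length(window)
  assert_that(n >= 2, "window must have at least 2 samples")
  assert_that(is_count(target_length), "`target_length` must be a positive count")
  if (n == target_length) return(window)
  g <- gcd(target_length, n)
  p <- target_length / g
  q <- n / g
  y <- signal::resample(window, p, q)
  # polyphase output length can differ by a sample; enforce the contract
  if (length(y) > target_length) {
    y <- y[seq_len(target_length)]
  } else if (length(y) < target_length) {
    y <- c(y, rep(y[length(y)], target_length - length(y)))
  }
  y
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Z-score standardize a window
#'
#' Centers and scales a window to mean 0 and unit variance,
#' x' = (x - mu) / sigma, using the population standard deviation. A
#' zero-variance (flat) window maps to all zeros rather than erroring, so
#' post-ictally flat seconds remain classifiable. Standardization makes the
#' classifier invariant to per-channel amplitude scale.
#'
#' @param window Non-empty numeric vector.
#' @return List with `x_prime` (standardized values), `mu`, `sigma`.
#' @export
#' @examples
#' standardize(c(1, 2, 3))
standardize <- function(window) {
  assert_that(length(window) >= 1, "window must be non-empty")
  assert_that(is.numeric(window) && all(is.finite(window)),
              "window must be finite numeric")
  mu <- mean(window)
  sigma <- sqrt(mean((window - mu)^2))
  x_prime <- if (sigma > 0) (window - mu) / sigma else rep(0, length(window))
  list(x_prime = x_prime, mu = mu, sigma = sigma)
}

# Row-wise standardization of a window matrix (per-window statistics).
standardize_rows <- function(mat) {
  mu <- rowMeans(mat)
  centered <- mat - mu
  sigma <- sqrt(rowMeans(centered^2))
  scale_ <- ifelse(sigma > 0, 1 / sigma, 0)
  centered * scale_
}

#' Binarize five-class labels to seizure / non-seizure
#'
#' Class 1 (ictal) maps to 1; classes 2-5 (non-seizure variants) map to 0.
#'
#' @param labels5 Integer vector with values in 1..5.
#' @return Integer vector of 0/1.
#' @export
#' @examples
#' binarize_labels(c(1, 2, 3, 4, 5))
binarize_labels <- function(labels5) {
  assert_that(all(labels5 %in% 1:5), "labels must lie in 1..5")
  as.integer(labels5 == 1)
}

#' Preprocessing configuration carried inside a model checkpoint
#'
#' Records every preprocessing choice needed to reproduce training-time
#' conditions at detection time.
#'
#' @param band_low,band_high Band-pass edges, Hz.
#' @param window_seconds Segmentation window, seconds.
#' @param target_length Samples per window after resampling.
#' @param standardization Either "per_window" (each window scaled by its own
#'   statistics; amplitude-scale invariant and applicable to a single second)
#'   or "per_column" (feature-column statistics frozen from the training
#'   split).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low = 0.53, band_high = 40,
                              window_seconds = 1, target_length = 178,
                              standardization = c("per_window", "per_column")) {
  standardization <- match.arg(standardization)
  structure(
    list(band_low = band_low, band_high = band_high,
         window_seconds = window_seconds, target_length = target_length,
         standardization = standardization),
    class = "preprocess_config"
  )
}
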