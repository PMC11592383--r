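#' Specification for the synthetic EEG generator
#'
#' Parameters of the surrogate EEG used to exercise the full pipeline when no
#' clinical recordings are available. Background activity is 1/f-shaped noise
#' plus an alpha rhythm; ictal activity is rhythmic spike-and-wave (a sharp
#' transient riding on a slow wave, classically near 3 Hz) whose amplitude
#' exceeds background by a programmable gain.
#'
#' @param sampling_rate Sampling rate in Hz. 178 Hz matches the single-channel
#'   training layout (178 samples per 1-s window); use 256 Hz for clinical-style
#'   multi-channel recordings.
#' @param window_seconds Window length in seconds used when cutting windows.
#' @param spike_wave_freq Fundamental frequency of the ictal spike-and-wave
#'   discharge, Hz.
#' @param ictal_amplitude_gain Ratio of ictal RMS amplitude to background RMS
#'   amplitude; must exceed 1.
#' @param background_alpha_freq Frequency of the background alpha rhythm, Hz.
#' @param noise_exponent Slope of the 1/f background noise spectrum
#'   (power ~ 1/f^noise_exponent).
#' @param background_rms Background RMS amplitude in microvolts.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec(seed = 1)
#' bg <- gen_background(178, spec)
synthetic_spec <- function(sampling_rate = 178,
                           window_seconds = 1,
                           spike_wave_freq = 3,
                           ictal_amplitude_gain = 4,
                           background_alpha_freq = 10,
                           noise_exponent = 1,
                           background_rms = 10,
                           seed = 1) {
  assert_that(sampling_rate > 2 * max(3 * spike_wave_freq, background_alpha_freq),
              "sampling_rate must exceed twice the highest generated frequency")
  assert_that(ictal_amplitude_gain > 1, "ictal_amplitude_gain must be > 1")
  assert_that(window_seconds > 0, "window_seconds must be positive")
  assert_that(background_rms > 0, "background_rms must be positive")
  assert_that(noise_exponent >= 0, "noise_exponent must be >= 0")
  structure(
    list(
      sampling_rate = sampling_rate,
      window_seconds = window_seconds,
      spike_wave_freq = spike_wave_freq,
      ictal_amplitude_gain = ictal_amplitude_gain,
      background_alpha_freq = background_alpha_freq,
      noise_exponent = noise_exponent,
      background_rms = background_rms,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# 1/f-shaped Gaussian noise via spectral shaping, band-limited to the EEG
# analysis band (the clinical pipeline filters to 0.53-40 Hz, and the
# single-channel source windows are band-limited at source); exact zero DC.
shaped_noise <- function(n, fs, exponent, fmin = 0.53, fmax = 40) {
  if (n == 1) return(0)
  half <- floor(n / 2)
  f <- (1:half) * fs / n
  amp <- f^(-exponent / 2) * (f >= fmin & f <= min(fmax, fs / 2))
  phase <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(half + 1)] <- spec
  if (n %% 2 == 0) {
    full[half + 1] <- complex(real = amp[half] * cos(phase[half]))
    if (half > 1) full[n:(n - half + 2)] <- Conj(spec[1:(half - 1)])
  } else {
    full[n:(n - half + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / max(stats::sd(x), .Machine$double.eps)
}

gen_background_core <- function(n_samples, spec, alpha_weight = 0.6) {
  fs <- spec$sampling_rate
  t <- (seq_len(n_samples) - 1) / fs
  noise <- shaped_noise(n_samples, fs, spec$noise_exponent)
  phase <- stats::runif(1, 0, 2 * pi)
  mod_phase <- stats::runif(1, 0, 2 * pi)
  envelope <- 1 + 0.3 * sin(2 * pi * 0.3 * t + mod_phase)
  alpha <- envelope * sin(2 * pi * spec$background_alpha_freq * t + phase)
  x <- noise + alpha_weight * alpha
  rms <- sqrt(mean(x^2))
  x / max(rms, .Machine$double.eps) * spec$background_rms
}

#' Generate synthetic background (non-seizure) EEG
#'
#' Zero-mean 1/f noise plus an amplitude-modulated alpha rhythm, scaled to the
#' spec's background RMS. Reproducible from the spec seed.
#'
#' @param n_samples Number of samples (>= 1).
#' @param spec A [synthetic_spec()].
#' @param alpha_weight Relative weight of the alpha component (internal knob
#'   used to produce background variants).
#' @return Numeric vector of length `n_samples` (microvolts).
#' @export
gen_background <- function(n_samples, spec, alpha_weight = 0.6) {
  assert_that(inherits(spec, "synthetic_spec"), "`spec` must be a synthetic_spec")
  assert_that(is_count(n_samples), "`n_samples` must be a positive count")
  with_seed(spec$seed, gen_background_core(n_samples, spec, alpha_weight))
}

gen_seizure_core <- function(n_samples, spec) {
  fs <- spec$sampling_rate
  f0 <- spec$spike_wave_freq
  t <- (seq_len(n_samples) - 1) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  # ictal rhythms are not metronomic: detune the fundamental a little and
  # let the phase wander slowly, so cut windows sample all phases
  f_eff <- f0 * stats::runif(1, 0.95, 1.05)
  fm <- stats::runif(1, 0.15, 0.45)
  pm <- 0.8 * sin(2 * pi * fm * t + stats::runif(1, 0, 2 * pi))
  phi <- 2 * pi * f_eff * t + phase + pm
  # slow-wave fundamental with weak harmonics
  wave <- sin(phi) + 0.4 * sin(2 * phi) + 0.2 * sin(3 * phi)
  # one sharp transient (spike) per cycle: narrow Gaussian bump
  cycle_pos <- (phi / (2 * pi)) %% 1                # position within cycle [0,1)
  dt <- (cycle_pos - 0.5) / f0                      # seconds from bump centre
  spike <- 1.2 * exp(-0.5 * (dt / 0.015)^2)
  rough <- 0.15 * shaped_noise(n_samples, fs, 0)
  x <- wave + spike - mean(spike) + rough
  rms <- sqrt(mean(x^2))
  # 15% headroom so every cut 1-s window still clears the gain contract
  x / max(rms, .Machine$double.eps) *
    (1.15 * spec$ictal_amplitude_gain * spec$background_rms)
}

#' Generate synthetic ictal (seizure) EEG
#'
#' Rhythmic spike-and-wave activity at the spec's fundamental frequency:
#' a slow-wave fundamental with 2nd/3rd harmonics plus one sharp Gaussian
#' transient per cycle, scaled so its RMS exceeds
#' `ictal_amplitude_gain` times the background RMS.
#'
#' @inheritParams gen_background
#' @return Numeric vector of length `n_samples` (microvolts).
#' @export
gen_seizure <- function(n_samples, spec) {
  assert_that(inherits(spec, "synthetic_spec"), "`spec` must be a synthetic_spec")
  assert_that(is_count(n_samples), "`n_samples` must be a positive count")
  with_seed(spec$seed, gen_seizure_core(n_samples, spec))
}

#' Generate a labeled single-channel window set in the UCI layout
#'
#' Emulates the five-class single-channel epilepsy-recognition table: each row
#' is one 1-s window of 178 samples plus an integer class label `y`.
#' Class 1 is ictal spike-and-wave; classes 2-5 are background variants
#' (2 and 3: background with raised variance, emulating pathological but
#' non-seizure tissue; 4: alpha-dominant "eyes closed"; 5: alpha-poor
#' "eyes open"). Only the binary contrast (1 vs rest) matters downstream.
#'
#' @param n_per_class Number of rows per class (>= 1).
#' @param spec A [synthetic_spec()]; its `sampling_rate` should be 178 so that
#'   one window is 1 s.
#' @param path Optional file path; if given, the table is written as a
#'   UCI-layout CSV (178 sample columns then a final `y` column).
#' @param n_samples Samples per row (default 178).
#' @return A tibble with columns `x1`..`x178` and `y` (integer in 1..5),
#'   `5 * n_per_class` rows in shuffled order.
#' @export
#' @examples
#' ws <- gen_uci_like(10, synthetic_spec(seed = 1))
#' table(ws$y)
gen_uci_like <- function(n_per_class, spec, path = NULL, n_samples = 178) {
  assert_that(inherits(spec, "synthetic_spec"), "`spec` must be a synthetic_spec")
  assert_that(is_count(n_per_class), "`n_per_class` must be a positive count")
  # Rows are produced the way the emulated source table was built: long
  # continuous segments of raw EEG (23 windows each) are band-pass filtered,
  # cut into non-overlapping 1-s windows and resampled to the row length.
  # Generating at the clinical rate and pushing every row through the same
  # filter/resample chain keeps the training distribution consistent with
  # windows cut from recordings at detection time.
  fs_gen <- 256
  gen_spec <- spec
  gen_spec$sampling_rate <- fs_gen
  win_per_seg <- 23L
  seg_len <- win_per_seg * fs_gen
  bf <- signal::butter(4, c(0.53, 40) / (fs_gen / 2), type = "pass")
  class_segment <- function(class, j) {
    s <- derive_seed(spec$seed, class * 100003 + j)
    raw <- with_seed(s, switch(
      class,
      gen_seizure_core(seg_len, gen_spec),
      1.6 * gen_background_core(seg_len, gen_spec),
      1.25 * gen_background_core(seg_len, gen_spec),
      gen_background_core(seg_len, gen_spec, alpha_weight = 1.2),
      gen_background_core(seg_len, gen_spec, alpha_weight = 0.3)
    ))
    filtfilt_padded(bf, raw, pad = 2 * fs_gen)
  }
  rows <- lapply(1:5, function(cl) {
    n_seg <- ceiling(n_per_class / win_per_seg)
    wins <- do.call(rbind, lapply(seq_len(n_seg), function(j) {
      win256 <- matrix(class_segment(cl, j), nrow = win_per_seg, byrow = TRUE)
      t(apply(win256, 1, resample_window, target_length = n_samples))
    }))
    wins[seq_len(n_per_class), , drop = FALSE]
  })
  x <- do.call(rbind, rows)
  y <- rep.int(1:5, rep(n_per_class, 5))
  ord <- with_seed(derive_seed(spec$seed, 999983), sample.int(nrow(x)))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  out <- tibble::as_tibble(as.data.frame(x), .name_repair = "minimal")
  names(out) <- paste0("x", seq_len(n_samples))
  out$y <- as.integer(y)
  if (!is.null(path)) write_uci_table(out, path)
  out
}

#' Seizure propagation schedule for the multi-channel generator
#'
#' Describes when each electrode site joins and leaves a seizure. Onset and
#' offset are snapped to whole seconds (onset rounded up, offset rounded
#' down), matching the 1-s non-overlapping windowing used downstream.
#'
#' @param sites Character vector of 10-20 site names (subset of
#'   [canonical_sites()]).
#' @param onset Numeric vector of per-site onset latencies in seconds.
#' @param offset Numeric vector of per-site offsets in seconds.
#' @param total_duration Total recording duration in seconds.
#' @return An object of class `propagation_schedule` (a tibble with attributes).
#' @export
#' @examples
#' sched <- propagation_schedule(c("F8", "T4"), onset = c(10, 12),
#'                               offset = c(20, 20), total_duration = 30)
propagation_schedule <- function(sites, onset, offset, total_duration) {
  assert_that(length(sites) == length(onset) && length(sites) == length(offset),
              "`sites`, `onset` and `offset` must have equal length")
  unknown <- setdiff(sites, canonical_sites())
  assert_that(length(unknown) == 0,
              paste0("unknown site name(s): ", paste(unknown, collapse = ", ")))
  assert_that(!anyDuplicated(sites), "duplicate site names in schedule")
  assert_that(all(onset >= 0) && all(onset < total_duration),
              "onsets must lie in [0, total_duration)")
  assert_that(all(offset > onset) && all(offset <= total_duration),
              "offsets must lie in (onset, total_duration]")
  out <- tibble::tibble(
    site = as.character(sites),
    onset = as.numeric(onset),
    offset = as.numeric(offset)
  )
  structure(out, total_duration = as.numeric(total_duration),
            class = c("propagation_schedule", class(out)))
}

#' Generate a 21-channel synthetic recording with ground truth
#'
#' Builds a full 10-20 montage recording: every channel carries background
#' activity; channels named in the schedule additionally carry ictal
#' spike-and-wave within their (whole-second-snapped) onset/offset interval.
#' A ground-truth site-by-second matrix marks exactly those seconds.
#'
#' @param schedule A [propagation_schedule()].
#' @param spec A [synthetic_spec()] (use `sampling_rate = 256` for
#'   clinical-style recordings).
#' @param path Optional EDF path; if given the recording is written as EDF and
#'   the ground truth as a JSON sidecar (`<path>.truth.json`,
#'   site -> seizure seconds).
#' @return A list with elements `recording` (an [eeg_recording()]) and
#'   `truth` (21 x seconds binary matrix, rows in canonical site order).
#' @export
#' @examples
#' sched <- propagation_schedule("F8", 5, 10, total_duration = 15)
#' sim <- gen_multichannel(sched, synthetic_spec(sampling_rate = 256, seed = 1))
#' dim(sim$truth)
gen_multichannel <- function(schedule, spec, path = NULL) {
  assert_that(inherits(schedule, "propagation_schedule"),
              "`schedule` must be a propagation_schedule")
  assert_that(inherits(spec, "synthetic_spec"), "`spec` must be a synthetic_spec")
  fs <- spec$sampling_rate
  total <- attr(schedule, "total_duration")
  n <- as.integer(round(total * fs))
  seconds <- as.integer(floor(total))
  sites <- canonical_sites()
  data <- matrix(0, nrow = length(sites), ncol = n, dimnames = list(sites, NULL))
  truth <- matrix(0L, nrow = length(sites), ncol = seconds,
                  dimnames = list(sites, NULL))
  for (i in seq_along(sites)) {
    site <- sites[i]
    x <- with_seed(derive_seed(spec$seed, i),
                   gen_background_core(n, spec))
    row <- match(site, schedule$site)
    if (!is.na(row)) {
      on_s <- as.integer(ceiling(schedule$onset[row]))
      off_s <- as.integer(floor(schedule$offset[row]))
      if (off_s > on_s) {
        len <- (off_s - on_s) * fs
        seiz <- with_seed(derive_seed(spec$seed, 1000 + i),
                          gen_seizure_core(len, spec))
        idx <- (on_s * fs + 1):(off_s * fs)
        x[idx] <- x[idx] + seiz
        truth[i, (on_s + 1):off_s] <- 1L
      }
    }
    data[i, ] <- x
  }
  ann <- if (nrow(schedule) > 0) {
    tibble::tibble(start = min(ceiling(schedule$onset)),
                   end = max(floor(schedule$offset)),
                   label = "seizure")
  } else NULL
  rec <- eeg_recording(data, sites, fs, annotations = ann)
  if (!is.null(path)) {
    write_edf(rec, path)
    truth_list <- lapply(seq_along(sites), function(i) {
      which(truth[i, ] == 1L) - 1L  # 0-based second indices
    })
    names(truth_list) <- sites
    jsonlite::write_json(truth_list, paste0(path, ".truth.json"))
  }
  list(recording = rec, truth = truth)
}
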