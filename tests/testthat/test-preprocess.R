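test_that("band-pass response meets the stopband and passband bounds", {
  # zero-phase (forward-backward) power response of the designed filter
  resp <- sozdetect:::bandpass_response(c(0.01, 50), fs = 256)
  expect_lt(20 * log10(resp[1]), -20)   # DC
  expect_lt(20 * log10(resp[2]), -20)   # 50 Hz
  mid <- sozdetect:::bandpass_response(seq(2, 30, by = 0.5), fs = 256)
  expect_true(all(abs(20 * log10(mid)) < 1))
})

test_that("band-pass attenuates out-of-band sinusoids and passes in-band ones", {
  fs <- 256
  t <- (0:(30 * fs - 1)) / fs
  mk <- function(x) eeg_recording(matrix(x, 1), "Cz", fs)
  steady <- (10 * fs):(20 * fs)  # interior: edge transients fully decayed
  out50 <- bandpass(mk(sin(2 * pi * 50 * t)))$data[1, steady]
  expect_lte(max(abs(out50)), 0.1)
  out10 <- bandpass(mk(sin(2 * pi * 10 * t)))$data[1, steady]
  expect_true(max(abs(out10)) > 0.9 && max(abs(out10)) < 1.1)
  outdc <- bandpass(mk(rep(1, length(t))))$data[1, steady]
  expect_lte(max(abs(outdc)), 0.1)
  expect_error(bandpass(mk(sin(t)), low = 0.53, high = 200), "Nyquist")
})

test_that("channel selection keeps exactly the 21 montage channels in order", {
  sched <- propagation_schedule("F8", 2, 4, total_duration = 5)
  sim <- gen_multichannel(sched, synthetic_spec(sampling_rate = 256, seed = 6))
  base <- sim$recording
  # clinical-style recording: montage channels plus T1/T2/ECG/EMG extras
  extra <- matrix(rnorm(4 * ncol(base$data)), 4)
  rec25 <- eeg_recording(rbind(base$data, extra),
                         c(base$channel_names, "T1", "T2", "ECG", "EMG"),
                         256)
  sel <- select_channels(rec25)
  expect_equal(nrow(sel$data), 21)
  expect_identical(sel$channel_names, canonical_sites())

  # shuffled channel order is normalized back to canonical
  ord <- rev(seq_len(21))
  shuffled <- eeg_recording(base$data[ord, ], base$channel_names[ord], 256)
  expect_identical(select_channels(shuffled)$data, base$data)

  missing <- eeg_recording(base$data[-21, ], base$channel_names[-21], 256)
  expect_error(select_channels(missing), "Pz")
})

test_that("segmentation arithmetic matches the windowing contract", {
  x <- gen_background(4097, synthetic_spec(seed = 8))
  w <- segment(x, sampling_rate = 178)
  expect_equal(dim(w), c(23, 178))
  # concatenating the windows reproduces the signal prefix (tail discarded)
  expect_identical(as.vector(t(w)), x[1:(23 * 178)])

  w2 <- segment(numeric(7680), sampling_rate = 256)
  expect_equal(dim(w2), c(30, 256))
  expect_error(segment(numeric(100), sampling_rate = 178), "shorter")
})

test_that("resampling is length-exact and frequency-preserving", {
  fs <- 256
  t <- (0:255) / fs
  w <- resample_window(sin(2 * pi * 5 * t), 178)
  expect_length(w, 178)
  mag <- Mod(stats::fft(w))[2:89]
  freqs <- (1:88) * 178 / 178
  expect_lt(abs(freqs[which.max(mag)] - 5), 0.5)

  same <- rnorm(178)
  expect_identical(resample_window(same, 178), same)
  expect_error(resample_window(3, 178), "2 samples")
})

test_that("z-score standardization satisfies its contract", {
  r <- standardize(c(1, 2, 3))
  expect_equal(mean(r$x_prime), 0)
  expect_equal(sqrt(mean(r$x_prime^2)), 1)   # population convention
  expect_equal(r$mu, 2)

  flat <- standardize(rep(5, 10))
  expect_identical(flat$x_prime, rep(0, 10))
  expect_equal(flat$sigma, 0)

  x <- rnorm(178, mean = 40, sd = 9)
  once <- standardize(x)$x_prime
  twice <- standardize(once)$x_prime
  expect_equal(twice, once, tolerance = 1e-12)
  expect_lt(abs(mean(once)), 1e-9)
  expect_lt(abs(mean(once^2) - 1), 1e-6)
})

test_that("label binarization keeps class 1 and zeroes the rest", {
  expect_identical(binarize_labels(c(1, 2, 3, 4, 5)), c(1L, 0L, 0L, 0L, 0L))
  expect_identical(binarize_labels(rep(1, 4)), rep(1L, 4))
  expect_error(binarize_labels(6), "1..5")
})
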