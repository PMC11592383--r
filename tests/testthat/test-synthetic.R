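test_that("generators are bit-identical under a fixed seed", {
  spec <- synthetic_spec(seed = 42)
  expect_identical(gen_background(256, spec), gen_background(256, spec))
  expect_identical(gen_seizure(256, spec), gen_seizure(256, spec))
  expect_identical(gen_uci_like(5, spec), gen_uci_like(5, spec))
  sched <- propagation_schedule("F8", 5, 10, total_duration = 15)
  s1 <- gen_multichannel(sched, synthetic_spec(sampling_rate = 256, seed = 3))
  s2 <- gen_multichannel(sched, synthetic_spec(sampling_rate = 256, seed = 3))
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$truth, s2$truth)
})

test_that("background is zero-mean with the requested length and scale", {
  spec <- synthetic_spec(seed = 7)
  expect_length(gen_background(256, spec), 256)
  x <- gen_background(10000, spec)
  expect_lt(abs(mean(x)) / sd(x), 0.05)
  expect_equal(sqrt(mean(x^2)), spec$background_rms, tolerance = 1e-8)
})

test_that("ictal activity peaks at the spike-wave frequency and clears the gain", {
  spec <- synthetic_spec(seed = 11)
  n <- 10 * spec$sampling_rate
  s <- gen_seizure(n, spec)
  mag <- Mod(stats::fft(s))[2:(n / 2)]
  freqs <- (1:(n / 2 - 1)) * spec$sampling_rate / n
  expect_lt(abs(freqs[which.max(mag)] - spec$spike_wave_freq), 0.5)
  # RMS contract holds for every generated ictal window
  ratios <- vapply(1:100, function(i) {
    sp <- synthetic_spec(seed = i)
    sqrt(mean(gen_seizure(178, sp)^2)) / sp$background_rms
  }, numeric(1))
  expect_true(all(ratios >= spec$ictal_amplitude_gain))
})

test_that("UCI-layout table has the forced shape and balanced labels", {
  ws <- gen_uci_like(100, synthetic_spec(seed = 1))
  expect_equal(dim(ws), c(500, 179))
  expect_equal(as.vector(table(ws$y)), rep(100L, 5))
  expect_identical(names(ws)[179], "y")
})

test_that("per-row RMS separates ictal windows from background", {
  ws <- fx_uci(100, seed = 1)
  rms <- sqrt(rowMeans(sozdetect:::window_matrix(ws)^2))
  yb <- binarize_labels(ws$y)
  # threshold fitted on the data itself: best split on sorted RMS
  thr <- seq(min(rms), max(rms), length.out = 200)
  acc <- vapply(thr, function(t) mean((rms > t) == yb), numeric(1))
  expect_gte(max(acc), 0.90)
})

test_that("multi-channel recordings follow the schedule exactly", {
  sched <- propagation_schedule(c("F8", "T4"), onset = c(10, 12),
                                offset = c(20, 20), total_duration = 30)
  sim <- gen_multichannel(sched, synthetic_spec(sampling_rate = 256, seed = 2))
  expect_equal(dim(sim$recording$data), c(21, 7680))
  expect_equal(dim(sim$truth), c(21, 30))
  # channels outside the schedule have all-zero ground truth
  off_sched <- setdiff(canonical_sites(), sched$site)
  expect_true(all(sim$truth[off_sched, ] == 0))
  # scheduled channels are marked exactly on their whole seconds
  expect_equal(which(sim$truth["F8", ] == 1), 11:20)  # 1-based columns
  expect_equal(which(sim$truth["T4", ] == 1), 13:20)
  # seizure seconds carry the amplitude contrast, background seconds do not
  f8 <- sim$recording$data["F8", ]
  ictal_rms <- sqrt(mean(f8[(10 * 256 + 1):(20 * 256)]^2))
  bg_rms <- sqrt(mean(f8[1:(10 * 256)]^2))
  expect_gte(ictal_rms / bg_rms, 2)
})

test_that("partial-second schedule boundaries are rounded to whole seconds", {
  sched <- propagation_schedule("C3", onset = 5.4, offset = 10.7,
                                total_duration = 12)
  sim <- gen_multichannel(sched, synthetic_spec(sampling_rate = 256, seed = 4))
  expect_equal(which(sim$truth["C3", ] == 1), 7:10)  # [6, 10) in 0-based s
})

test_that("schedules reject unknown sites and bad intervals", {
  expect_error(propagation_schedule("Q7", 1, 5, 10), "unknown site")
  expect_error(propagation_schedule("F8", -1, 5, 10), "onset")
  expect_error(propagation_schedule("F8", 5, 4, 10), "offset")
  expect_error(synthetic_spec(ictal_amplitude_gain = 1), "gain")
  expect_error(synthetic_spec(sampling_rate = 15), "sampling_rate")
})
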