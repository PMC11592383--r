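test_that("detection matrix has the site-by-second shape contract", {
  model <- fx_detect_model()
  sched <- propagation_schedule(c("F8", "T4"), onset = c(10, 12),
                                offset = c(20, 20), total_duration = 30)
  sim <- gen_multichannel(sched, synthetic_spec(sampling_rate = 256, seed = 21))
  dm <- detect_sites(sim$recording, model)
  expect_s3_class(dm, "detection_matrix")
  expect_equal(dim(dm$verdicts), c(21, 30))
  expect_identical(dm$site_names, canonical_sites())
  expect_identical(dm$verdicts,
                   matrix(as.integer(dm$probabilities >= 0.5), 21,
                          dimnames = dimnames(dm$verdicts)))
})

test_that("detection agrees with ground truth on a seeded scenario", {
  model <- fx_detect_model()
  sched <- propagation_schedule(c("F8", "T4"), onset = c(10, 12),
                                offset = c(20, 20), total_duration = 30)
  sim <- gen_multichannel(sched, synthetic_spec(sampling_rate = 256, seed = 21))
  dm <- detect_sites(sim$recording, model)
  expect_gte(mean(dm$verdicts == sim$truth), 0.90)
})

test_that("an all-background recording stays almost unflagged", {
  model <- fx_detect_model()
  quiet <- propagation_schedule(character(0), numeric(0), numeric(0), 30)
  sim <- gen_multichannel(quiet, synthetic_spec(sampling_rate = 256, seed = 22))
  dm <- detect_sites(sim$recording, model)
  expect_lte(mean(dm$verdicts), 0.05)
})

test_that("detection is channel-order invariant and deterministic", {
  model <- fx_detect_model()
  sched <- propagation_schedule("C4", 5, 12, total_duration = 15)
  sim <- gen_multichannel(sched, synthetic_spec(sampling_rate = 256, seed = 23))
  dm1 <- detect_sites(sim$recording, model)
  ord <- sample(21)
  shuffled <- eeg_recording(sim$recording$data[ord, ],
                            sim$recording$channel_names[ord], 256)
  dm2 <- detect_sites(shuffled, model)
  expect_equal(dm1$probabilities, dm2$probabilities, tolerance = 1e-12)
  dm3 <- detect_sites(sim$recording, model)
  expect_identical(dm1$probabilities, dm3$probabilities)
  expect_error(detect_sites(eeg_recording(sim$recording$data[-1, ],
                                          sim$recording$channel_names[-1], 256),
                            model), "missing channel")
})

test_that("marginal counts conserve the total of flagged cells", {
  probs <- matrix(0, 21, 40, dimnames = list(canonical_sites(), NULL))
  probs[3, 7] <- 0.9
  dm <- detection_matrix(probs, canonical_sites())
  s <- summarize_counts(dm)
  expect_equal(sum(s$per_second$n_sites), 1)
  expect_equal(sum(s$per_site$n_seconds), 1)
  expect_equal(s$per_second$n_sites[7], 1)
  expect_equal(s$per_site$n_seconds[3], 1)

  zero <- detection_matrix(matrix(0, 21, 10), canonical_sites())
  sz <- summarize_counts(zero)
  expect_true(all(sz$per_second$n_sites == 0))
  expect_true(all(sz$per_site$n_seconds == 0))

  set.seed(2)
  rnd <- detection_matrix(matrix(runif(21 * 15), 21), canonical_sites())
  sr <- summarize_counts(rnd)
  expect_equal(sum(sr$per_second$n_sites), sum(rnd$verdicts))
  expect_equal(sum(sr$per_site$n_seconds), sum(rnd$verdicts))
})
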