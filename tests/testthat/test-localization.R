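dm_from_flags <- function(flags, seconds = 40) {
  # flags: named list second -> site vector
  probs <- matrix(0, 21, seconds, dimnames = list(canonical_sites(), NULL))
  for (s in names(flags)) probs[flags[[s]], as.integer(s)] <- 0.9
  detection_matrix(probs, canonical_sites())
}

test_that("onset extraction finds the first flagged second and its sites", {
  dm <- dm_from_flags(list(
    `15` = c("Pz", "C4", "P4", "F8", "T4"),
    `17` = c("F4"), `25` = c("F3"), `30` = c("F4", "F8")
  ))
  on <- onset_sites(dm, onset_window_s = 5)
  expect_equal(on$onset_second, 15)
  expect_setequal(on$sites, c("Pz", "C4", "P4", "F8", "T4", "F4"))

  single <- dm_from_flags(list(`8` = "F7"))
  expect_identical(onset_sites(single)$sites, "F7")
  zero <- detection_matrix(matrix(0, 21, 10), canonical_sites())
  expect_error(onset_sites(zero), "no seizure")
})

test_that("terminal extraction unions the last flagged window", {
  dm <- dm_from_flags(list(`10` = c("F8", "T4"), `20` = "C3",
                           `36` = "F4", `38` = c("F4", "F8")))
  expect_setequal(terminal_sites(dm, 5), c("F4", "F8"))
  all_last <- dm_from_flags(list(`40` = canonical_sites()))
  expect_setequal(terminal_sites(all_last), canonical_sites())
  zero <- detection_matrix(matrix(0, 21, 10), canonical_sites())
  expect_error(terminal_sites(zero), "no seizure")
})

test_that("hemisphere verdicts reproduce the clinical site-set examples", {
  # focal right: onset includes midline Pz yet lateralized sites are right
  expect_equal(classify_soz(c("Pz", "C4", "P4", "F8", "T4"), c("F4", "F8")),
               "right hemisphere")
  # bilateral onset
  expect_equal(classify_soz(c("F7", "F3", "C3", "T3", "F4", "C4", "T4", "F8")),
               "both hemispheres")
  expect_error(classify_soz("Cz"), "midline")
  expect_error(classify_soz(character(0)), "non-empty")
})

test_that("seizure typing separates focal from generalized onsets", {
  expect_equal(classify_seizure_type(c("C4", "P4", "F8", "T4", "Pz")), "focal")
  expect_equal(classify_seizure_type(c("O1", "O2", "T5", "T6", "P4")),
               "generalized")
  expect_equal(classify_seizure_type("F7"), "focal")
  expect_error(classify_seizure_type(c("Fz", "Cz")), "midline")
})

test_that("verdicts mirror under a left-right flip of the site sets", {
  mirror <- function(sites) {
    swap <- c(Fp1 = "Fp2", Fp2 = "Fp1", F3 = "F4", F4 = "F3", C3 = "C4",
              C4 = "C3", P3 = "P4", P4 = "P3", O1 = "O2", O2 = "O1",
              F7 = "F8", F8 = "F7", T3 = "T4", T4 = "T3", T5 = "T6",
              T6 = "T5", A1 = "A2", A2 = "A1", Fz = "Fz", Cz = "Cz",
              Pz = "Pz")
    unname(swap[sites])
  }
  sets <- list(c("F8", "F4"), c("C3", "P3", "Pz"), c("F7", "F8"),
               c("T4", "T6", "O2", "Cz"))
  for (s in sets) {
    v <- classify_soz(s)
    vm <- classify_soz(mirror(s))
    flip <- c("left hemisphere" = "right hemisphere",
              "right hemisphere" = "left hemisphere",
              "both hemispheres" = "both hemispheres")
    expect_equal(vm, unname(flip[v]))
    expect_equal(classify_seizure_type(mirror(s)), classify_seizure_type(s))
  }
})

test_that("soz_report assembles the full verdict from a matrix", {
  dm <- dm_from_flags(list(`15` = c("Pz", "C4", "P4", "F8", "T4"),
                           `18` = c("F4", "C4"),
                           `25` = canonical_sites(),
                           `36` = c("F4", "F8")))
  rep <- soz_report(dm)
  expect_equal(rep$onset_second, 15)
  expect_equal(rep$soz_verdict, "right hemisphere")
  expect_equal(rep$seizure_type, "focal")
  g <- glance(rep)
  expect_equal(g$soz_verdict, "right hemisphere")
  td <- tidy(rep)
  expect_true(all(td$site %in% canonical_sites()))
})

test_that("topomap render states track the flags exactly", {
  dm <- dm_from_flags(list(`5` = "F8"), seconds = 12)
  out <- render_topomap(dm, c(3, 5))
  s3 <- out$states[out$states$second == 3, ]
  expect_equal(sum(s3$flagged), 0)
  s5 <- out$states[out$states$second == 5, ]
  expect_equal(sum(s5$flagged), 1)
  expect_equal(s5$site[s5$flagged == 1], "F8")

  five <- render_topomap(dm, c(1, 3, 5, 7, 9))
  expect_length(five$plots, 5)
  expect_s3_class(five$sequence, "ggplot")
  expect_error(render_topomap(dm, 99), "out of matrix range")
})

test_that("end-to-end synthetic recovery finds a right focal seizure", {
  # seizure seeded in {F8, F4} with later bilateral spread; majority vote
  # over three recording seeds
  model <- fx_detect_model()
  verdicts <- character(0); types <- character(0)
  for (s in c(7, 17, 27)) {
    sim <- gen_multichannel(fx_focal_schedule(),
                            synthetic_spec(sampling_rate = 256, seed = s))
    rep <- soz_report(detect_sites(sim$recording, model))
    verdicts <- c(verdicts, rep$soz_verdict)
    types <- c(types, rep$seizure_type)
  }
  expect_gte(sum(verdicts == "right hemisphere"), 2)
  expect_gte(sum(types == "focal"), 2)
})
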