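Package: sozdetect
Title: Seizure Onset Zone Detection from Scalp EEG with a Single-Channel 1D CNN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects seizure onset zones (SOZ) from multi-channel scalp EEG.
    A one-dimensional convolutional neural network classifies single-channel
    one-second EEG windows as seizure or non-seizure; applied channel-wise
    across the 21 electrodes of the international 10-20 montage it yields
    per-second seizure-site grids, from which hemisphere-level onset zones
    and focal versus generalized seizure type are inferred and rendered as
    topographic maps. Includes preprocessing (band-pass filtering, 1-s
    segmentation, resampling, z-score standardization), SMOTE class
    rebalancing, stratified 10-fold cross-validation with early stopping,
    a discrete-wavelet-transform plus random-forest baseline, EDF and
    UCI-layout CSV readers and writers, and a synthetic EEG generator with
    programmable seizure propagation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    signal,
    ranger,
    generics,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
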