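---
title: "Seizure onset zone detection from channel-wise scalp EEG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure onset zone detection from channel-wise scalp EEG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the method

Before epilepsy surgery, clinicians must localize the seizure onset zone
(SOZ) — the cortical area where seizures begin, the practical surrogate for
the epileptogenic zone. Scalp EEG (sEEG) on the international 10–20 montage
is the non-invasive window onto this question. `sozdetect` implements a
channel-wise localization strategy: a *single-channel* classifier decides,
for every electrode and every second, whether that second of signal is
ictal; the resulting site-by-second grid is then read topographically to
find where the seizure starts, how it spreads, and where it persists.

The pipeline has four stages:

1. **Preprocessing.** Each channel is band-pass filtered to 0.53–40 Hz (the
   band carrying seizure-relevant content), cut into non-overlapping 1-s
   windows, resampled to 178 samples per window, and z-score standardized,
   $x' = (x - \mu)/\sigma$, per window.
2. **Classification.** A small 1-D convolutional network maps each
   standardized 178-sample window to a seizure probability. The layer stack
   is three convolutions (20 kernels of length 5, stride 1, valid padding,
   ReLU, dropout 0.5 after each during training), max-pooling (pool 2), a
   flatten layer, a 50-unit ReLU dense layer and one sigmoid output. With a
   178-sample input the per-layer lengths are
   178 → 174 → 170 → 166 → 83×20 → 1660 → 50 → 1. A window is called
   seizure when its probability is at least 0.5; the tie at exactly 0.5
   goes to the seizure class, favouring sensitivity.
3. **Detection.** The trained single-channel model is applied independently
   to all 21 montage channels (Fp1, Fp2, F3, F4, C3, C4, P3, P4, O1, O2,
   F7, F8, T3, T4, T5, T6, A1, A2, Fz, Cz, Pz — T1/T2, ECG and EMG
   channels are dropped), yielding a 21 × seconds verdict matrix.
   Conceptually this is "21 identical models"; since identical training on
   identical data yields identical weights, one weight set is applied to
   every channel.
4. **Localization.** The onset second is the first second with any flagged
   site; the onset site set is the union of flagged sites in the following
   5 s, and the terminal set the union over the last 5 flagged seconds.
   Midline sites (Fz, Cz, Pz) carry no laterality information and are
   excluded from hemisphere votes. If lateralized onset sites appear in
   both hemispheres the SOZ verdict is "both hemispheres" and the seizure
   type *generalized*; otherwise the verdict is the single onset
   hemisphere and the type *focal*. Terminal evidence refines a unilateral
   onset but never overrides it — a focal seizure that secondarily
   generalizes still lateralizes by its onset.

## Training protocol

Training uses a labeled single-channel window table (178 sample columns
plus a class label in 1..5, where class 1 is ictal; labels are binarized
1 ↔ seizure, {2,3,4,5} → 0, leaving a 1:4 class imbalance). The protocol
is: a stratified 80/20 train+validation/test split; SMOTE rebalancing
(synthetic minority windows interpolated between a minority row and one of
its 5 nearest minority neighbours); stratified 10-fold cross-validation on
the 80% with per-fold early-stopped training (Adam, learning rate 0.001,
batch size 256, up to 200 epochs, patience 16 on validation loss with
best-weights restoration, binary cross-entropy loss); fold selection by
validation *sensitivity* (missing a seizure is the costly error); and a
final evaluation of the selected weights on the untouched test set.
Metrics are accuracy, sensitivity and specificity in percent.

Two protocol details were genuinely open and are settled as follows:

* **SMOTE scope.** Rebalancing "the training and validation sets" jointly
  lets synthetic neighbours of validation rows leak into training folds,
  inflating validation metrics. The default `smote_scope = "train_only"`
  applies SMOTE inside each fold to the training part only, so validation
  metrics are computed on untouched rows; `"train_plus_val"` reproduces
  the literal pooled behaviour for comparison.
* **Early-stopping monitor.** Validation loss with best-weights
  restoration — the standard overfitting guard when no monitor is named.

The optimizer's second-order constants are the conventional Adam defaults
(moment decays 0.9/0.999, epsilon 1e-7) and are recorded in the checkpoint
together with the full preprocessing configuration, so detection always
reproduces training-time preprocessing exactly.

No deep-learning framework is involved: the forward pass, backpropagation,
dropout, Adam and early stopping are implemented in the package (im2col
patch extraction in C++ via Rcpp, matrix products through BLAS). A
nested-loop reference implementation serves as an independent oracle in
the tests; gradient correctness was verified against central differences
to ~1e-8 during development.

## The synthetic data generator

The clinical multi-channel recordings this method targets are private, so
the package ships a first-class generator that emulates the statistical
contrast the classifier relies on:

* **Background** is 1/f-shaped Gaussian noise (default exponent 1) plus a
  10 Hz alpha rhythm with slow amplitude modulation, scaled to 10 µV RMS,
  band-limited to the 0.53–40 Hz analysis band (the public single-channel
  source data are band-limited at source, and the clinical path filters to
  the same band).
* **Ictal activity** is rhythmic ~3 Hz spike-and-wave: a slow-wave
  fundamental with 2nd/3rd harmonics plus one sharp Gaussian transient
  (σ = 15 ms) per cycle. The fundamental is detuned by ±5% per realization
  and its phase wanders slowly, because real ictal rhythms are not
  metronomic — without this, 1-s windows at exactly 3 cycles/window would
  all share one phase. Ictal RMS is scaled to 1.15 × gain × background RMS
  (default gain 4), so every cut window clears the gain contract.
* **Single-channel tables** mimic the public five-class layout: class 1
  ictal, classes 2–3 background with raised variance (pathological but
  non-seizure tissue), class 4 alpha-dominant ("eyes closed"), class 5
  alpha-poor ("eyes open"). Rows are cut as 23 consecutive windows from
  long continuous segments — as the real table was — after generating at
  the clinical 256 Hz rate and pushing each segment through the same
  band-pass/segment/resample chain the detector applies. This keeps the
  training distribution consistent with windows cut from recordings; early
  versions that synthesized rows independently at 178 Hz left a
  train/detection domain gap that showed up as a ~2% false-alarm rate.
* **Multi-channel recordings** place background on all 21 sites and add
  ictal activity on scheduled sites within per-site onset/offset intervals.
  Schedule boundaries are snapped to whole seconds (onset up, offset down)
  so the ground-truth site-by-second matrix is exact at the 1-s windowing
  resolution.

What the generator does *not* emulate: eye-blink/EMG artifacts, electrode
pops, volume conduction between channels, inter-patient variability, and
the morphological diversity of real ictal patterns. Passing tests on this
surrogate therefore demonstrate that the pipeline's machinery is correct
and that the method recovers planted spatial structure — not that the
classifier would reach the same numbers on clinical EEG.

## Numerical choices

* **Filter realization:** 4th-order Butterworth band-pass applied
  forward-backward (zero phase), since phase distortion would shift spike
  timing across window boundaries. Signals are odd-reflection padded
  (2/0.53 ≈ 3.8 s per end) before filtering so the slow high-pass
  transient never contaminates the first and last analysis windows. The
  zero-phase response is −20 dB or better at DC and 50 Hz and flat within
  ±1 dB across 2–30 Hz.
* **Resampling:** polyphase rational resampling (256 → 178 is the reduced
  ratio 89/128) with anti-aliasing; output length is enforced exactly.
* **Standardization:** per-window statistics with the population (n)
  standard deviation. Per-window scaling is the only choice applicable to
  a single detected second and makes the classifier invariant to
  per-channel amplitude scale; a per-column mode (statistics frozen from
  the training split) is available in the preprocessing configuration.
  All-flat windows (σ = 0), which occur post-ictally, map to all zeros
  rather than erroring.
* **Segmentation:** non-overlapping windows aligned to the recording
  start; trailing partial windows are dropped.
* **Weight initialization:** Glorot-uniform with an explicit seed; every
  random step (split, folds, SMOTE, shuffling, dropout) derives from one
  master seed, so runs are bit-reproducible.

## The wavelet baseline

The classical comparison — manual feature extraction plus tree ensembles —
is included: each window is decomposed with a periodized Daubechies
pyramid (default db4, 4 levels; the exact recipe behind the published
comparison is not specified, so these are declared, configurable
defaults), and five statistics (mean, SD, energy, max, min) per subband
(approximation first) feed a 100-tree random forest or extremely
randomized trees classifier (via `ranger`, seeded, single-threaded), under
the same stratified 80/20 split. The published baseline percentages are
treated as indicative only; this module reproduces the *method*, not the
numbers.

## Problem sizes used by tests and the acceptance script

The full clinical-scale protocol (11,500 rows, 200 epochs, batch 256) is
what the defaults describe; the shipped tests and `scripts/acceptance.R`
exercise the identical code paths at desk scale, chosen once as follows:

* train→evaluate: 200 windows/class (1,000 rows), single 90/10 holdout
  validation, batch 64, up to 25 epochs — small batches give the optimizer
  enough updates per epoch on a small set; training converges to
  perfect separation of the synthetic classes well within that budget.
* 10-fold cross-validation: 100 windows/class, up to 15 epochs per fold.
* channel-wise detection: a detection-grade model trained on 400
  windows/class (the per-cell false-alarm budget over a 21 × 40 grid is
  stricter than a test-set accuracy bound), then 40-s recordings with a
  focal right-frontal onset ({F8, F4}) and staged bilateral spread,
  repeated over three recording seeds with majority voting.

The headline clinical-data metrics (test accuracy 98.70%, sensitivity
97.53%, specificity 98.98%; 10-fold means 99.13/99.32/98.94) require the
external public single-channel dataset, which is not redistributed here.
When a local copy is supplied to `read_uci_table()` the full protocol at
the default hyperparameters is expected to land within about one
percentage point of each; this is documented rather than asserted by the
test suite.

## Known limitations

* The hemisphere rule is a deliberate formalization: one lateralized site
  in each hemisphere within the onset window already yields "both
  hemispheres". No quantitative threshold separating a stray contralateral
  site from genuine bilateral onset is established; the onset/terminal
  window length (5 s) is configurable but its default is a granularity
  choice, not a fitted parameter.
* Verdicts are per-second and unsmoothed by design; a single false-alarm
  cell before the true onset shifts the reported onset second. The
  detection-grade training size keeps the false-alarm rate near zero on
  the synthetic conditions, but clinical deployments would likely add
  temporal persistence rules, which are out of scope here.
* The EDF writer/reader covers the plain 16-bit continuous-recording
  subset of the format (one sampling rate, no EDF+ annotation streams).
* Lobe-level inference beyond naming persistent sites, source imaging and
  MRI fusion are out of scope.
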