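# DWT + tree-ensemble baseline: the classical manual-feature-extraction
# comparison for the CNN. Wavelet features are computed with a periodized
# pyramid using Daubechies filter banks.

daubechies_filter <- function(wavelet) {
  switch(wavelet,
    haar = ,
    db1 = c(1, 1) / sqrt(2),
    db2 = c(0.48296291314469025, 0.8365163037378079,
            0.22414386804185735, -0.12940952255092145),
    db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    stop("unknown wavelet family: ", wavelet, call. = FALSE)
  )
}

# One periodized analysis step: returns approximation and detail, each of
# length ceiling(n/2). Odd-length inputs wrap their first sample.
dwt_step <- function(x, h) {
  if (length(x) %% 2 == 1) x <- c(x, x[1])
  n <- length(x)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  idx <- outer(seq(0, n - 2, by = 2), seq_len(L) - 1, "+") %% n + 1
  xm <- matrix(x[idx], nrow = n / 2)
  list(approx = as.vector(xm %*% h), detail = as.vector(xm %*% g))
}

#' Specification of the wavelet feature extractor
#'
#' @param wavelet Wavelet family: "db4" (default), "db2", "db1"/"haar".
#' @param levels Number of decomposition levels (>= 1).
#' @param stats Per-subband statistics; any of "mean", "sd", "energy",
#'   "max", "min".
#' @return An object of class `dwt_feature_spec`. The feature length is
#'   `(levels + 1) * length(stats)`.
#' @export
dwt_feature_spec <- function(wavelet = "db4", levels = 4,
                             stats = c("mean", "sd", "energy", "max", "min")) {
  assert_that(is_count(levels), "`levels` must be a positive count")
  daubechies_filter(wavelet)  # validates the name
  known <- c("mean", "sd", "energy", "max", "min")
  assert_that(all(stats %in% known),
              paste0("unknown statistic(s): ",
                     paste(setdiff(stats, known), collapse = ", ")))
  structure(list(wavelet = wavelet, levels = as.integer(levels),
                 stats = stats),
            class = "dwt_feature_spec")
}

subband_stats <- function(x, stats) {
  vapply(stats, function(s) {
    switch(s,
           mean = mean(x),
           sd = stats::sd(x),
           energy = sum(x^2),
           max = max(x),
           min = min(x))
  }, numeric(1))
}

#' Discrete-wavelet-transform features of one window
#'
#' Decomposes a window into `levels` detail subbands plus the final
#' approximation (periodized Daubechies pyramid) and concatenates summary
#' statistics per subband, approximation first, then details from the
#' coarsest to the finest level.
#'
#' @param window Numeric vector (long enough for `levels` decompositions
#'   with the chosen filter).
#' @param spec A [dwt_feature_spec()].
#' @return Named numeric vector of length `(levels + 1) * length(stats)`.
#' @export
#' @examples
#' length(dwt_features(sin(1:178), dwt_feature_spec()))  # 25
dwt_features <- function(window, spec = dwt_feature_spec()) {
  h <- daubechies_filter(spec$wavelet)
  x <- as.numeric(window)
  details <- vector("list", spec$levels)
  for (lev in seq_len(spec$levels)) {
    assert_that(length(x) >= length(h),
                "window too short for the requested decomposition depth")
    st <- dwt_step(x, h)
    details[[lev]] <- st$detail
    x <- st$approx
  }
  bands <- c(list(x), rev(details))  # cA_L, cD_L, ..., cD_1
  names(bands) <- c(paste0("cA", spec$levels),
                    paste0("cD", seq(spec$levels, 1)))
  out <- unlist(lapply(names(bands), function(nm) {
    v <- subband_stats(bands[[nm]], spec$stats)
    names(v) <- paste0(nm, "_", spec$stats)
    v
  }))
  out
}

dwt_feature_matrix <- function(mat, spec) {
  t(apply(mat, 1, dwt_features, spec = spec))
}

#' Train a DWT + tree-ensemble baseline classifier
#'
#' Extracts wavelet features from each window and fits a random forest or an
#' extremely randomized trees (Extra Trees) classifier, using the same
#' stratified 80/20 split protocol as the CNN; test metrics come from the
#' shared evaluation module.
#'
#' @param windows Labeled window tibble (`x1..x178`, `y`).
#' @param classifier "random_forest" or "extra_trees".
#' @param feature_spec A [dwt_feature_spec()].
#' @param config A [train_config()] (only split fraction and seed are used).
#' @param num_trees Number of trees.
#' @return An object of class `dwt_baseline` with elements `fit` (ranger
#'   model), `metrics` (test-set tibble), `classifier`, `feature_spec`.
#' @export
train_baseline <- function(windows, classifier = c("random_forest", "extra_trees"),
                           feature_spec = dwt_feature_spec(),
                           config = train_config(), num_trees = 100) {
  classifier <- match.arg(classifier)
  yb <- binary_labels_of(windows)
  assert_that(length(unique(yb)) == 2, "both classes must be present")
  parts <- split_train_test(windows, config)
  f_train <- dwt_feature_matrix(window_matrix(parts$train), feature_spec)
  f_test <- dwt_feature_matrix(window_matrix(parts$test), feature_spec)
  df_train <- as.data.frame(f_train)
  df_train$y <- factor(binary_labels_of(parts$train), levels = c(0, 1))
  splitrule <- if (classifier == "extra_trees") "extratrees" else "gini"
  fit <- ranger::ranger(
    y ~ ., data = df_train, num.trees = num_trees, splitrule = splitrule,
    seed = config$seed, num.threads = 1
  )
  pred <- stats::predict(fit, data = as.data.frame(f_test))$predictions
  metrics <- seizure_metrics(as.integer(as.character(pred)),
                             binary_labels_of(parts$test))
  structure(
    list(fit = fit, metrics = metrics, classifier = classifier,
         feature_spec = feature_spec),
    class = "dwt_baseline"
  )
}

#' @export
print.dwt_baseline <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<dwt_baseline> %s on %s features\n", x$classifier,
              x$feature_spec$wavelet))
  cat(sprintf("test: accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              m$accuracy, m$sensitivity, m$specificity))
  invisible(x)
}

#' One-row summary of a baseline fit
#' @param x A `dwt_baseline`.
#' @param ... Unused.
#' @return One-row tibble with classifier name and test metrics.
#' @method glance dwt_baseline
#' @export
glance.dwt_baseline <- function(x, ...) {
  tibble::tibble(classifier = x$classifier,
                 wavelet = x$feature_spec$wavelet,
                 accuracy = x$metrics$accuracy,
                 sensitivity = x$metrics$sensitivity,
                 specificity = x$metrics$specificity)
}
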