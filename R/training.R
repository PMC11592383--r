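#' Training configuration for the seizure classifier
#'
#' Defaults follow the best-performing protocol: Adam with learning rate
#' 0.001, batch size 256, up to 200 epochs with early stopping at patience
#' 16 (monitoring validation loss, best weights restored), stratified 80/20
#' train+validation/test split, 10-fold cross-validation on the 80%, SMOTE
#' rebalancing, and sensitivity as the fold-selection metric.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param n_folds Number of cross-validation folds (1 = single 90/10
#'   holdout validation split instead of CV).
#' @param test_fraction Fraction of rows held out as the test set.
#' @param smote_scope "train_only" applies SMOTE inside each fold to the
#'   training part only, so validation metrics are computed on untouched
#'   rows; "train_plus_val" rebalances the pooled train+validation set
#'   before folding (synthetic rows may then fall into validation folds).
#' @param selection_metric Metric used to pick the best fold
#'   ("sensitivity", "accuracy" or "specificity").
#' @param k_neighbors SMOTE neighbourhood size.
#' @param threshold Decision threshold for verdicts.
#' @param seed Master seed; every random step (split, folds, SMOTE,
#'   initialization, shuffling, dropout) derives from it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 256,
                         max_epochs = 200, patience = 16, n_folds = 10,
                         test_fraction = 0.2,
                         smote_scope = c("train_only", "train_plus_val"),
                         selection_metric = "sensitivity",
                         k_neighbors = 5, threshold = 0.5, seed = 1) {
  smote_scope <- match.arg(smote_scope)
  assert_that(test_fraction > 0 && test_fraction < 1,
              "test_fraction must lie in (0, 1)")
  assert_that(is_count(n_folds), "n_folds must be a positive count")
  assert_that(selection_metric %in% c("sensitivity", "accuracy", "specificity"),
              "unknown selection metric")
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         n_folds = as.integer(n_folds), test_fraction = test_fraction,
         smote_scope = smote_scope, selection_metric = selection_metric,
         k_neighbors = as.integer(k_neighbors), threshold = threshold,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

binary_labels_of <- function(windows) {
  if ("y_binary" %in% names(windows)) return(as.integer(windows$y_binary))
  binarize_labels(windows$y)
}

#' Stratified train/test split of a labeled window set
#'
#' Splits rows into a train+validation set and a test set, stratified by the
#' binary seizure label so the class ratio is preserved in both parts.
#' Seeded and reproducible. The original row indices of each part are
#' attached as attribute `row_indices`.
#'
#' @param windows A labeled window tibble (columns `x1..x178`, `y`).
#' @param config A [train_config()].
#' @return List with elements `train` and `test` (tibbles).
#' @export
split_train_test <- function(windows, config = train_config()) {
  yb <- binary_labels_of(windows)
  assert_that(length(unique(yb)) == 2,
              "both classes must be present to split")
  test_idx <- with_seed(derive_seed(config$seed, 1), {
    unlist(lapply(unique(yb), function(cl) {
      rows <- which(yb == cl)
      sample(rows, round(length(rows) * config$test_fraction))
    }))
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(windows)), test_idx)
  out <- list(train = windows[train_idx, , drop = FALSE],
              test = windows[test_idx, , drop = FALSE])
  attr(out, "row_indices") <- list(train = train_idx, test = test_idx)
  out
}

#' SMOTE: synthetic minority oversampling
#'
#' Balances a binary-labeled feature matrix by interpolating between
#' minority-class samples: each synthetic row is x_i + lambda * (x_nn - x_i)
#' for a minority row x_i, one of its `k_neighbors` nearest minority
#' neighbours x_nn (Euclidean), and lambda drawn uniformly from [0, 1].
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Binary 0/1 label vector.
#' @param k_neighbors Neighbourhood size; the minority class must have more
#'   than `k_neighbors` members.
#' @param seed Integer seed.
#' @return List with `x` (original rows then synthetic rows), `y`, and
#'   `synthesis` (tibble with columns `parent`, `neighbor`, `lambda`,
#'   row indices into the original `x`; `NULL` when the input was already
#'   balanced).
#' @export
smote <- function(x, y, k_neighbors = 5, seed = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  assert_that(all(y %in% c(0L, 1L)), "labels must be binary (0/1)")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == n0) return(list(x = x, y = y, synthesis = NULL))
  minority <- if (n1 < n0) 1L else 0L
  min_rows <- which(y == minority)
  n_min <- length(min_rows)
  n_needed <- abs(n0 - n1)
  assert_that(n_min > k_neighbors,
              "minority class must have more than k_neighbors members")
  xm <- x[min_rows, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
  synth <- with_seed(seed, {
    parent <- rep_len(seq_len(n_min), n_needed)
    neighbor <- nn[cbind(parent, sample.int(k_neighbors, n_needed, replace = TRUE))]
    lambda <- stats::runif(n_needed)
    new_x <- xm[parent, , drop = FALSE] +
      lambda * (xm[neighbor, , drop = FALSE] - xm[parent, , drop = FALSE])
    list(x = new_x,
         log = tibble::tibble(parent = min_rows[parent],
                              neighbor = min_rows[neighbor],
                              lambda = lambda))
  })
  list(x = rbind(x, synth$x),
       y = c(y, rep(minority, n_needed)),
       synthesis = synth$log)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_update <- function(weights, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

#' Train one classifier on a fixed train/validation split
#'
#' Minimizes mean binary cross-entropy with the Adam optimizer on shuffled
#' minibatches, with dropout active during training. Training stops early
#' when the validation loss has not improved for `patience` epochs; the
#' weights from the best-validation-loss epoch are restored. Non-finite loss
#' aborts with an error.
#'
#' @param spec A [cnn_spec()].
#' @param x_train,y_train Standardized training windows (matrix) and 0/1
#'   labels.
#' @param x_val,y_val Validation windows and labels.
#' @param config A [train_config()].
#' @param seed Seed for initialization, shuffling and dropout (defaults to
#'   the config seed).
#' @return List with `weights`, `history` (per-epoch tibble), `best_epoch`,
#'   `epochs_run`.
#' @export
train_one <- function(spec, x_train, y_train, x_val, y_val,
                      config = train_config(), seed = NULL) {
  seed <- seed %||% config$seed
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  n <- nrow(x_train)
  with_seed(seed, {
    weights <- init_cnn_weights(spec, seed = derive_seed(seed, 7))
    state <- list(m = zero_like_weights(weights), v = zero_like_weights(weights))
    best <- list(loss = Inf, weights = weights, epoch = 0L)
    history <- vector("list", config$max_epochs)
    t_step <- 0L
    wait <- 0L
    epochs_run <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        fwd <- cnn_forward_cache(weights, x_train[idx, , drop = FALSE], spec,
                                 training = TRUE)
        loss <- bce_loss(fwd$p, y_train[idx])
        if (!is.finite(loss)) stop("training diverged: non-finite loss",
                                   call. = FALSE)
        grads <- cnn_backward(weights, fwd, y_train[idx], spec)
        t_step <- t_step + 1L
        upd <- adam_update(weights, grads, state, config$learning_rate, t_step)
        weights <- upd$weights; state <- upd$state
        batch_losses <- c(batch_losses, loss)
      }
      val_p <- cnn_forward_cache(weights, x_val, spec, training = FALSE)$p
      val_loss <- bce_loss(val_p, y_val)
      vm <- seizure_metrics(as.integer(val_p >= config$threshold), y_val)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = mean(batch_losses), val_loss = val_loss,
        val_accuracy = vm$accuracy, val_sensitivity = vm$sensitivity,
        val_specificity = vm$specificity
      )
      epochs_run <- epoch
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, weights = weights, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    list(weights = best$weights,
         history = dplyr::bind_rows(history[seq_len(epochs_run)]),
         best_epoch = best$epoch, epochs_run = epochs_run)
  })
}

# Stratified fold assignment: per class, shuffle then deal round-robin.
fold_assignment <- function(yb, n_folds, seed) {
  folds <- integer(length(yb))
  with_seed(seed, {
    for (cl in unique(yb)) {
      rows <- which(yb == cl)
      rows <- sample(rows)
      folds[rows] <- rep_len(seq_len(n_folds), length(rows))
    }
  })
  folds
}

#' K-fold cross-validation of the seizure classifier
#'
#' Stratified k-fold cross-validation on a (train+validation) window set.
#' Depending on `config$smote_scope`, SMOTE is applied inside each fold to
#' the training part only (default) or once to the pooled set before
#' folding. Each fold trains with early stopping and reports validation
#' accuracy, sensitivity and specificity in percent.
#'
#' @param windows Labeled window tibble.
#' @param config A [train_config()] (`n_folds` >= 2).
#' @param spec A [cnn_spec()].
#' @return A tibble with one row per fold: `fold`, `accuracy`,
#'   `sensitivity`, `specificity`, `best_epoch`, `epochs_run`, and a
#'   `weights` list-column.
#' @export
cross_validate <- function(windows, config = train_config(), spec = cnn_spec()) {
  assert_that(config$n_folds >= 2, "cross-validation needs n_folds >= 2")
  x <- standardize_rows(window_matrix(windows))
  yb <- binary_labels_of(windows)
  assert_that(nrow(x) >= config$n_folds, "too few rows for the requested folds")
  if (config$smote_scope == "train_plus_val") {
    balanced <- smote(x, yb, config$k_neighbors, seed = derive_seed(config$seed, 2))
    x <- balanced$x; yb <- balanced$y
  }
  folds <- fold_assignment(yb, config$n_folds, derive_seed(config$seed, 3))
  res <- lapply(seq_len(config$n_folds), function(f) {
    tr <- folds != f
    x_tr <- x[tr, , drop = FALSE]; y_tr <- yb[tr]
    if (config$smote_scope == "train_only") {
      balanced <- smote(x_tr, y_tr, config$k_neighbors,
                        seed = derive_seed(config$seed, 100 + f))
      x_tr <- balanced$x; y_tr <- balanced$y
    }
    fit <- train_one(spec, x_tr, y_tr, x[!tr, , drop = FALSE], yb[!tr],
                     config, seed = derive_seed(config$seed, 200 + f))
    val_pred <- as.integer(cnn_forward(fit$weights, x[!tr, , drop = FALSE]) >=
                             config$threshold)
    m <- seizure_metrics(val_pred, yb[!tr])
    tibble::tibble(fold = f, accuracy = m$accuracy,
                   sensitivity = m$sensitivity, specificity = m$specificity,
                   best_epoch = fit$best_epoch, epochs_run = fit$epochs_run,
                   weights = list(fit$weights), history = list(fit$history))
  })
  dplyr::bind_rows(res)
}

#' Select the best cross-validation fold
#'
#' Picks the fold maximizing the selection metric (sensitivity by default,
#' so the chosen model favours catching seizures); ties are broken by higher
#' accuracy, then by lower fold index.
#'
#' @param fold_results Tibble returned by [cross_validate()].
#' @param metric One of "sensitivity", "accuracy", "specificity".
#' @return The selected row of `fold_results` (one-row tibble).
#' @export
select_best <- function(fold_results, metric = "sensitivity") {
  assert_that(nrow(fold_results) > 0, "no fold results to select from")
  assert_that(metric %in% names(fold_results), "unknown selection metric")
  ord <- order(-fold_results[[metric]], -fold_results$accuracy,
               fold_results$fold)
  fold_results[ord[1], , drop = FALSE]
}

#' Train the seizure classifier end to end
#'
#' The full protocol: stratified 80/20 train+validation/test split, SMOTE
#' class rebalancing, stratified k-fold cross-validation with early-stopped
#' Adam training on the 80%, selection of the best fold by sensitivity, and
#' a final evaluation of the selected weights on the untouched test set.
#' With `config$n_folds = 1` a single 90/10 holdout validation split
#' replaces cross-validation.
#'
#' @param windows Labeled window tibble (columns `x1..x178`, `y` in 1..5 or
#'   binary).
#' @param config A [train_config()].
#' @param spec A [cnn_spec()].
#' @param preprocess A [preprocess_config()] recorded in the model so that
#'   detection reproduces training-time preprocessing.
#' @return An object of class `seizure_cnn` with elements `weights`, `spec`,
#'   `config`, `preprocess`, `folds` (fold metrics), `best_fold`,
#'   `test_metrics`, `history`.
#' @export
train_seizure_cnn <- function(windows, config = train_config(),
                              spec = cnn_spec(),
                              preprocess = preprocess_config()) {
  parts <- split_train_test(windows, config)
  x_test <- standardize_rows(window_matrix(parts$test))
  y_test <- binary_labels_of(parts$test)
  if (config$n_folds >= 2) {
    folds <- cross_validate(parts$train, config, spec)
    best <- select_best(folds, config$selection_metric)
    weights <- best$weights[[1]]
    history <- best$history[[1]]
    fold_table <- dplyr::select(folds, -"weights", -"history")
    best_fold <- best$fold
  } else {
    x <- standardize_rows(window_matrix(parts$train))
    yb <- binary_labels_of(parts$train)
    hold <- fold_assignment(yb, 10, derive_seed(config$seed, 3)) == 1
    balanced <- smote(x[!hold, , drop = FALSE], yb[!hold], config$k_neighbors,
                      seed = derive_seed(config$seed, 2))
    fit <- train_one(spec, balanced$x, balanced$y, x[hold, , drop = FALSE],
                     yb[hold], config, seed = derive_seed(config$seed, 201))
    weights <- fit$weights
    history <- fit$history
    fold_table <- NULL
    best_fold <- NA_integer_
  }
  test_pred <- as.integer(cnn_forward(weights, x_test) >= config$threshold)
  structure(
    list(weights = weights, spec = spec, config = config,
         preprocess = preprocess, folds = fold_table, best_fold = best_fold,
         test_metrics = seizure_metrics(test_pred, y_test),
         history = history),
    class = "seizure_cnn"
  )
}

#' @export
print.seizure_cnn <- function(x, ...) {
  cat("<seizure_cnn> trained single-channel seizure classifier\n")
  m <- x$test_metrics
  cat(sprintf("test: accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              m$accuracy, m$sensitivity, m$specificity))
  if (!is.null(x$folds)) {
    cat(sprintf("cross-validation: %d folds, best fold %d (by %s)\n",
                nrow(x$folds), x$best_fold, x$config$selection_metric))
  }
  invisible(x)
}

#' Per-fold cross-validation metrics of a fitted classifier
#' @param x A `seizure_cnn`.
#' @param ... Unused.
#' @return Tibble of fold metrics (percent).
#' @method tidy seizure_cnn
#' @export
tidy.seizure_cnn <- function(x, ...) {
  if (is.null(x$folds)) {
    return(tibble::tibble(fold = integer(), accuracy = numeric(),
                          sensitivity = numeric(), specificity = numeric()))
  }
  x$folds
}

#' One-row summary of a fitted classifier
#' @param x A `seizure_cnn`.
#' @param ... Unused.
#' @return One-row tibble: test metrics, number of folds, best fold.
#' @method glance seizure_cnn
#' @export
glance.seizure_cnn <- function(x, ...) {
  tibble::tibble(
    accuracy = x$test_metrics$accuracy,
    sensitivity = x$test_metrics$sensitivity,
    specificity = x$test_metrics$specificity,
    n_folds = if (is.null(x$folds)) 1L else nrow(x$folds),
    best_fold = x$best_fold
  )
}
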