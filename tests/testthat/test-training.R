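test_that("stratified split preserves counts and class ratios", {
  ws <- fx_uci(100, seed = 1)  # 500 rows, 100 seizure / 400 background
  cfg <- train_config(seed = 4)
  parts <- split_train_test(ws, cfg)
  expect_equal(nrow(parts$train), 400)
  expect_equal(nrow(parts$test), 100)
  expect_equal(sum(binarize_labels(parts$test$y)), 20)   # 1:4 ratio kept
  expect_equal(sum(binarize_labels(parts$train$y)), 80)
  # disjoint and exhaustive by original row identity
  idx <- attr(parts, "row_indices")
  expect_length(intersect(idx$train, idx$test), 0)
  expect_setequal(c(idx$train, idx$test), seq_len(500))
  # seeded: identical split on re-run
  parts2 <- split_train_test(ws, cfg)
  expect_identical(attr(parts2, "row_indices"), idx)
  one_class <- ws[binarize_labels(ws$y) == 0, ]
  expect_error(split_train_test(one_class, cfg), "both classes")
})

test_that("SMOTE balances classes with convex synthetic rows", {
  set.seed(10)
  x <- matrix(rnorm(50 * 6), 50)
  y <- c(rep(0L, 40), rep(1L, 10))
  out <- smote(x, y, k_neighbors = 5, seed = 2)
  expect_equal(as.vector(table(out$y)), c(40L, 40L))
  expect_equal(nrow(out$x), 80)
  # every synthetic row solves x_new = x_i + lambda (x_nn - x_i) with one
  # lambda shared across all coordinates, lambda in [0, 1]
  syn <- out$synthesis
  for (j in seq_len(nrow(syn))) {
    xi <- x[syn$parent[j], ]; xn <- x[syn$neighbor[j], ]
    x_new <- out$x[50 + j, ]
    lam <- (x_new - xi) / (xn - xi)
    expect_equal(max(lam) - min(lam), 0, tolerance = 1e-10)
    expect_true(lam[1] >= 0 && lam[1] <= 1)
    expect_equal(lam[1], syn$lambda[j], tolerance = 1e-10)
  }
  # already balanced input passes through untouched
  bal <- smote(x[1:20, ], rep(c(0L, 1L), each = 10), seed = 2)
  expect_identical(bal$x, x[1:20, ])
  expect_null(bal$synthesis)
  expect_error(smote(x[1:44, ], c(rep(0L, 40), rep(1L, 4)), k_neighbors = 5),
               "k_neighbors")
})

test_that("training minimizes loss, early-stops and reproduces exactly", {
  ws <- fx_uci(40, seed = 2)
  x <- sozdetect:::standardize_rows(sozdetect:::window_matrix(ws))
  yb <- binarize_labels(ws$y)
  val <- seq(1, 200, by = 4)
  cfg <- train_config(max_epochs = 6, patience = 2, batch_size = 64, seed = 9)
  spec <- cnn_spec()
  fit <- train_one(spec, x[-val, ], yb[-val], x[val, ], yb[val], cfg)
  expect_lte(fit$history$loss[fit$best_epoch], fit$history$loss[1])
  expect_lte(fit$epochs_run, cfg$max_epochs)
  # identical seed, identical history
  fit2 <- train_one(spec, x[-val, ], yb[-val], x[val, ], yb[val], cfg)
  expect_identical(fit$history, fit2$history)
  # patience: a hopeless validation target stops before max_epochs
  cfg_stop <- train_config(max_epochs = 30, patience = 2, batch_size = 64,
                           seed = 9, learning_rate = 0)
  fit3 <- train_one(spec, x[-val, ], yb[-val], x[val, ], yb[val], cfg_stop)
  expect_lt(fit3$epochs_run, 30)
})

test_that("fold assignment partitions every class across folds", {
  yb <- rep(c(0L, 1L), c(80, 20))
  folds <- sozdetect:::fold_assignment(yb, 10, seed = 3)
  expect_length(folds, 100)
  expect_setequal(unique(folds), 1:10)
  # validation folds are disjoint and their union is the whole set
  expect_equal(sum(table(folds)), 100)
  # stratification: each fold holds 2 seizure rows
  expect_true(all(tapply(yb, folds, sum) == 2))
})

test_that("cross-validation reaches high validation accuracy on separable data", {
  ws <- fx_uci(100, seed = 5)
  parts <- split_train_test(ws, train_config(seed = 6))
  cfg <- train_config(n_folds = 10, max_epochs = 15, patience = 6,
                      batch_size = 64, seed = 6)
  folds <- cross_validate(parts$train, cfg)
  expect_equal(nrow(folds), 10)
  expect_true(all(folds$epochs_run <= cfg$max_epochs))
  expect_true(all(folds$accuracy >= 0 & folds$accuracy <= 100))
  expect_gte(mean(folds$accuracy), 95)
})

test_that("fold selection maximizes sensitivity with deterministic ties", {
  res <- tibble::tibble(fold = 1:3,
                        sensitivity = c(99.0, 99.72, 98.5),
                        accuracy = c(99.0, 99.12, 99.5))
  expect_equal(select_best(res)$fold, 2)
  ties <- tibble::tibble(fold = 1:3, sensitivity = c(99, 99, 99),
                         accuracy = c(98, 98, 98))
  expect_equal(select_best(ties)$fold, 1)
  expect_equal(select_best(ties[3, ])$fold, 3)
  expect_error(select_best(ties[0, ]), "no fold")
})

test_that("test rows never enter SMOTE or training", {
  ws <- fx_uci(50, seed = 3)
  cfg <- train_config(seed = 8)
  parts <- split_train_test(ws, cfg)
  idx <- attr(parts, "row_indices")
  # SMOTE inputs are exactly the train rows: every synthesis parent points
  # into the train part, never the test part
  x <- sozdetect:::standardize_rows(sozdetect:::window_matrix(parts$train))
  yb <- binarize_labels(parts$train$y)
  out <- smote(x, yb, seed = 8)
  expect_true(all(out$synthesis$parent <= nrow(parts$train)))
  expect_length(intersect(idx$train, idx$test), 0)
})
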