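test_that("default architecture reproduces the published shape chain", {
  spec <- cnn_spec()
  expect_equal(spec$shapes$conv_lengths, c(174, 170, 166))
  expect_equal(spec$shapes$pooled, 83)
  expect_equal(spec$shapes$flatten, 1660)
  expect_equal(spec$shapes$dense, 50)
  expect_equal(spec$shapes$output, 1)
  # the flattened width is what the dense layer actually consumes
  w <- sozdetect:::init_cnn_weights(spec, 1)
  expect_equal(nrow(w$Wd), 1660)
})

test_that("valid convolution matches hand-computed cross-correlation", {
  out <- conv1d(matrix(rnorm(178), ncol = 1),
                array(rnorm(5 * 1 * 20), c(5, 1, 20)), bias = numeric(20))
  expect_equal(dim(out), c(174, 20))

  # identity-tap kernel slides the input
  expect_equal(conv1d(1:6, c(1, 0, 0, 0, 0), bias = 0, activation = "linear"),
               c(1, 2))
  # zero weights and bias give zero output
  expect_true(all(conv1d(rnorm(20), rep(0, 5), bias = 0) == 0))
  expect_error(conv1d(1:3, rep(1, 5)), "shorter")
})

test_that("max pooling halves length and keeps window maxima", {
  x <- matrix(rnorm(166 * 20), 166)
  expect_equal(dim(maxpool1d(x, 2)), c(83, 20))
  expect_equal(maxpool1d(c(1, 3, 2, 0)), c(3, 2))
  mono <- maxpool1d(1:10)
  expect_true(all(diff(mono) > 0))
})

test_that("activations satisfy their algebraic identities", {
  expect_equal(relu(c(-3, 2)), c(0, 2))
  expect_equal(sigmoid(0), 0.5)
  x <- rnorm(50) * 5
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 50))
  expect_true(all(relu(x) >= 0))
  expect_true(all(sigmoid(x) > 0 & sigmoid(x) < 1))
})

test_that("inference is deterministic, order-invariant and correctly tied", {
  spec <- cnn_spec()
  w <- sozdetect:::init_cnn_weights(spec, 3)
  x <- matrix(rnorm(178 * 8), 8)
  expect_identical(cnn_forward(w, x), cnn_forward(w, x))
  # batch order invariance
  ord <- sample(8)
  expect_equal(cnn_forward(w, x[ord, ]), cnn_forward(w, x)[ord],
               tolerance = 1e-12)
  # zero weights: sigmoid(0) = 0.5 exactly, and the 0.5 tie maps to verdict 1
  w0 <- sozdetect:::zero_like_weights(w)
  expect_equal(cnn_forward(w0, x), rep(0.5, 8))
  expect_equal(cnn_predict(w0, x), rep(1L, 8))
  expect_equal(cnn_predict(w, x, threshold = 1), rep(0L, 8))
  expect_error(cnn_forward(w, matrix(0, 2, 100)), "178")
})

test_that("vectorized forward pass matches the nested-loop oracle", {
  toy <- cnn_spec(input_length = 10, kernels_per_layer = 2, kernel_length = 3,
                  dense_units = 4, dropout_rate = 0)
  w <- sozdetect:::init_cnn_weights(toy, 21)
  x <- matrix(rnorm(10 * 6), 6)
  expect_equal(cnn_forward(w, x), naive_forward(w, x, toy), tolerance = 1e-6)
})

test_that("dropout acts only in training mode", {
  spec <- cnn_spec()
  w <- sozdetect:::init_cnn_weights(spec, 5)
  x <- matrix(rnorm(178 * 4), 4)
  p_inf <- cnn_forward(w, x)
  set.seed(1); p_tr1 <- cnn_forward(w, x, training = TRUE)
  set.seed(2); p_tr2 <- cnn_forward(w, x, training = TRUE)
  expect_false(identical(p_tr1, p_tr2))
  expect_identical(cnn_forward(w, x), p_inf)
})
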