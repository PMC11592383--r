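#' Specification of the 1D convolutional seizure classifier
#'
#' The default architecture stacks three convolutional layers (20 kernels of
#' length 5, stride 1, valid padding, ReLU, each followed by dropout 0.5
#' during training), one max-pooling layer (pool 2), a flatten layer, a
#' 50-unit ReLU dense layer and a single sigmoid output unit. With a
#' 178-sample input window the layer lengths are 178 -> 174 -> 170 -> 166 ->
#' 83x20 -> 1660 -> 50 -> 1.
#'
#' @param input_length Samples per input window.
#' @param n_conv_layers Number of convolutional layers.
#' @param kernels_per_layer Kernels (output channels) per convolutional layer.
#' @param kernel_length Kernel length (samples).
#' @param conv_stride Convolution stride.
#' @param dropout_rate Dropout probability after each convolutional layer
#'   (training only).
#' @param pool_size Max-pooling window.
#' @param dense_units Units in the penultimate dense layer.
#' @param output_units Output units (1 for binary seizure detection).
#' @param threshold Decision threshold on the output probability; a window is
#'   called seizure when its probability is greater than or equal to this.
#' @return An object of class `cnn_spec` with a derived `shapes` element.
#' @export
#' @examples
#' cnn_spec()$shapes$flatten  # 1660
cnn_spec <- function(input_length = 178, n_conv_layers = 3,
                     kernels_per_layer = 20, kernel_length = 5,
                     conv_stride = 1, dropout_rate = 0.5, pool_size = 2,
                     dense_units = 50, output_units = 1, threshold = 0.5) {
  assert_that(is_count(input_length) && is_count(n_conv_layers) &&
                is_count(kernels_per_layer) && is_count(kernel_length) &&
                is_count(pool_size) && is_count(dense_units) &&
                is_count(output_units), "architecture sizes must be positive counts")
  assert_that(conv_stride == 1, "only stride-1 convolution is supported")
  assert_that(dropout_rate >= 0 && dropout_rate < 1,
              "dropout_rate must lie in [0, 1)")
  lens <- input_length
  for (i in seq_len(n_conv_layers)) {
    nxt <- lens[length(lens)] - kernel_length + 1
    assert_that(nxt >= 1, "input too short for the convolutional stack")
    lens <- c(lens, nxt)
  }
  pooled <- floor(lens[length(lens)] / pool_size)
  assert_that(pooled >= 1, "input too short for pooling")
  flatten <- pooled * kernels_per_layer
  spec <- structure(
    list(input_length = input_length, n_conv_layers = n_conv_layers,
         kernels_per_layer = kernels_per_layer, kernel_length = kernel_length,
         conv_stride = conv_stride, dropout_rate = dropout_rate,
         pool_size = pool_size, dense_units = dense_units,
         output_units = output_units, threshold = threshold,
         shapes = list(conv_lengths = lens[-1], pooled = pooled,
                       flatten = flatten, dense = dense_units,
                       output = output_units)),
    class = "cnn_spec"
  )
  spec
}

#' @export
print.cnn_spec <- function(x, ...) {
  k <- x$kernels_per_layer
  cat("<cnn_spec>\n")
  cat(sprintf("  %-14s %-12s %-10s %s\n", "Layer", "Kernels", "Size", "Output"))
  for (i in seq_len(x$n_conv_layers)) {
    cat(sprintf("  %-14s %-12d %-10s %d x %d (ReLU)\n", paste0("Conv", i), k,
                paste0(x$kernel_length, " x 1"), x$shapes$conv_lengths[i], k))
  }
  cat(sprintf("  %-14s %-12s %-10s %d x %d\n", "Maxpool1", "-",
              paste0(x$pool_size, " x 1"), x$shapes$pooled, k))
  cat(sprintf("  %-14s %-12s %-10s %d\n", "Flatten", "-", "-", x$shapes$flatten))
  cat(sprintf("  %-14s %-12s %-10s %d (ReLU)\n", "Dense", "-", "-", x$dense_units))
  cat(sprintf("  %-14s %-12s %-10s %d (Sigmoid)\n", "Output", "-", "-",
              x$output_units))
  invisible(x)
}

#' Rectified linear activation
#' @param x Numeric input.
#' @return `max(0, x)` elementwise.
#' @export
relu <- function(x) pmax(x, 0)

#' Sigmoid activation
#' @param x Numeric input.
#' @return `1 / (1 + exp(-x))` elementwise, in (0, 1).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' One-dimensional valid cross-correlation layer
#'
#' Computes the valid (no padding) convolution of an input feature map with a
#' bank of kernels, adds the per-kernel bias, and optionally applies ReLU.
#' For an input of length L and kernels of length k the output has length
#' L - k + 1.
#'
#' @param input Numeric vector (single channel) or L x C matrix.
#' @param kernel Numeric vector (single in/out channel) or a k x C x K array.
#' @param bias Numeric vector of length K (recycled scalar allowed).
#' @param stride Output stride.
#' @param activation "relu" or "linear".
#' @return Numeric (L - k + 1)/stride x K matrix (a vector when K = 1 and the
#'   input was a vector).
#' @export
#' @examples
#' conv1d(1:6, c(1, 0, 0, 0, 0), bias = 0, activation = "linear")  # 1 2
conv1d <- function(input, kernel, bias = 0, stride = 1,
                   activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  vec_in <- is.null(dim(input))
  X <- if (vec_in) matrix(input, ncol = 1) else as.matrix(input)
  W <- if (is.null(dim(kernel))) array(kernel, c(length(kernel), 1, 1)) else kernel
  assert_that(length(dim(W)) == 3, "`kernel` must be a vector or k x C x K array")
  k <- dim(W)[1]; C <- dim(W)[2]; K <- dim(W)[3]
  assert_that(ncol(X) == C, "input channel count does not match kernel")
  L <- nrow(X)
  assert_that(L >= k, "input shorter than kernel")
  if (length(bias) == 1) bias <- rep(bias, K)
  assert_that(length(bias) == K, "bias length must equal kernel count")
  pos <- seq(1, L - k + 1, by = stride)
  Wm <- matrix(aperm(W, c(2, 1, 3)), k * C, K)  # row index c + (t-1)*C
  P <- matrix(0, length(pos), k * C)
  for (t in seq_len(k)) {
    P[, ((t - 1) * C + 1):(t * C)] <- X[pos + t - 1, , drop = FALSE]
  }
  Z <- P %*% Wm + rep(bias, each = length(pos))
  out <- if (activation == "relu") pmax(Z, 0) else Z
  if (vec_in && K == 1) as.vector(out) else out
}

#' One-dimensional max pooling
#'
#' Slides a non-overlapping window of `pool_size` along the length axis and
#' keeps the maximum; trailing samples that do not fill a window are dropped.
#'
#' @param x Numeric vector or L x K matrix.
#' @param pool_size Pooling window length.
#' @return Pooled vector or floor(L / pool_size) x K matrix.
#' @export
#' @examples
#' maxpool1d(c(1, 3, 2, 0))  # 3 2
maxpool1d <- function(x, pool_size = 2) {
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, ncol = 1) else as.matrix(x)
  L <- nrow(X)
  assert_that(L >= pool_size, "input shorter than the pooling window")
  Lp <- floor(L / pool_size)
  out <- matrix(-Inf, Lp, ncol(X))
  for (j in seq_len(pool_size)) {
    out <- pmax(out, X[seq(j, by = pool_size, length.out = Lp), , drop = FALSE])
  }
  if (vec_in) as.vector(out) else out
}

# ---- weights ---------------------------------------------------------------

# Glorot-uniform initialization of all layer weights, seeded.
init_cnn_weights <- function(spec, seed = 1) {
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  with_seed(seed, {
    k <- spec$kernel_length; K <- spec$kernels_per_layer
    w <- list()
    cin <- 1
    for (i in seq_len(spec$n_conv_layers)) {
      w[[paste0("W", i)]] <- glorot(k * cin, K, k * cin, k * K)
      w[[paste0("b", i)]] <- numeric(K)
      cin <- K
    }
    w$Wd <- glorot(spec$shapes$flatten, spec$dense_units,
                   spec$shapes$flatten, spec$dense_units)
    w$bd <- numeric(spec$dense_units)
    w$Wo <- glorot(spec$dense_units, spec$output_units,
                   spec$dense_units, spec$output_units)
    w$bo <- numeric(spec$output_units)
    structure(w, spec = spec, class = "cnn_weights")
  })
}

zero_like_weights <- function(w) {
  out <- lapply(unclass(w), function(p) p * 0)
  attributes(out) <- attributes(w)
  out
}

# ---- batch forward / backward ---------------------------------------------

# X3: (N, L, C) -> list(A3 (N, Lo, K), P, mask)
conv_fwd <- function(X3, W, b) {
  d <- dim(X3); N <- d[1]; L <- d[2]; C <- d[3]
  k <- nrow(W) / C; K <- ncol(W)
  Lo <- L - k + 1
  P <- im2col_nlc(X3, as.integer(k))
  Z <- P %*% W + rep(b, each = N * Lo)
  A <- pmax(Z, 0)
  list(A3 = array(A, c(N, Lo, K)), P = P, mask = Z > 0,
       dims = c(N = N, L = L, C = C, k = k, Lo = Lo, K = K))
}

conv_bwd <- function(cache, W, dA3) {
  dm <- cache$dims
  N <- dm["N"]; L <- dm["L"]; C <- dm["C"]; k <- dm["k"]; Lo <- dm["Lo"]; K <- dm["K"]
  dZ <- matrix(dA3, N * Lo, K) * cache$mask
  dW <- crossprod(cache$P, dZ)
  db <- colSums(dZ)
  dP <- dZ %*% t(W)
  dX3 <- col2im_nlc(dP, as.integer(N), as.integer(L), as.integer(C),
                    as.integer(k))
  list(dW = dW, db = db, dX3 = dX3)
}

pool_fwd <- function(X3, pool_size) {
  d <- dim(X3); N <- d[1]; L <- d[2]; K <- d[3]
  Lp <- floor(L / pool_size)
  A <- array(-Inf, c(N, Lp, K))
  argmax <- array(1L, c(N, Lp, K))
  for (j in seq_len(pool_size)) {
    cand <- X3[, seq(j, by = pool_size, length.out = Lp), , drop = FALSE]
    better <- cand > A
    A[better] <- cand[better]
    argmax[better] <- j
  }
  list(A3 = A, argmax = argmax, dims = c(N = N, L = L, K = K, Lp = Lp,
                                         ps = pool_size))
}

pool_bwd <- function(cache, dA3) {
  dm <- cache$dims
  dX3 <- array(0, c(dm["N"], dm["L"], dm["K"]))
  for (j in seq_len(dm["ps"])) {
    sel <- cache$argmax == j
    slice <- array(0, dim(dA3))
    slice[sel] <- dA3[sel]
    dX3[, seq(j, by = dm["ps"], length.out = dm["Lp"]), ] <- slice
  }
  dX3
}

# Full forward pass with cache; dropout masks drawn from the current RNG
# stream when training = TRUE.
cnn_forward_cache <- function(weights, X, spec, training = FALSE) {
  N <- nrow(X)
  A3 <- array(X, c(N, ncol(X), 1))
  caches <- list()
  keep <- 1 - spec$dropout_rate
  for (i in seq_len(spec$n_conv_layers)) {
    cc <- conv_fwd(A3, weights[[paste0("W", i)]], weights[[paste0("b", i)]])
    A3 <- cc$A3
    if (training && spec$dropout_rate > 0) {
      mask <- array((stats::runif(length(A3)) < keep) / keep, dim(A3))
      A3 <- A3 * mask
      cc$dropout <- mask
    }
    caches[[i]] <- cc
  }
  pc <- pool_fwd(A3, spec$pool_size)
  d <- dim(pc$A3)
  flat <- matrix(aperm(pc$A3, c(1, 3, 2)), N, d[2] * d[3])
  Zd <- flat %*% weights$Wd + rep(weights$bd, each = N)
  Ad <- pmax(Zd, 0)
  Zo <- Ad %*% weights$Wo + rep(weights$bo, each = N)
  p <- sigmoid(Zo)
  list(p = as.vector(p), caches = caches, pool = pc, flat = flat,
       Zd = Zd, Ad = Ad, N = N, pooled_dim = d)
}

# Gradient of mean binary cross-entropy w.r.t. all weights.
cnn_backward <- function(weights, fwd, y, spec) {
  N <- fwd$N
  g <- list()
  dZo <- matrix((fwd$p - y) / N, N, 1)
  g$Wo <- crossprod(fwd$Ad, dZo)
  g$bo <- colSums(dZo)
  dAd <- dZo %*% t(weights$Wo)
  dZd <- dAd * (fwd$Zd > 0)
  g$Wd <- crossprod(fwd$flat, dZd)
  g$bd <- colSums(dZd)
  dflat <- dZd %*% t(weights$Wd)
  d <- fwd$pooled_dim
  dpool <- aperm(array(dflat, c(N, d[3], d[2])), c(1, 3, 2))
  dA3 <- pool_bwd(fwd$pool, dpool)
  for (i in rev(seq_len(spec$n_conv_layers))) {
    cc <- fwd$caches[[i]]
    if (!is.null(cc$dropout)) dA3 <- dA3 * cc$dropout
    bb <- conv_bwd(cc, weights[[paste0("W", i)]], dA3)
    g[[paste0("W", i)]] <- bb$dW
    g[[paste0("b", i)]] <- bb$db
    dA3 <- bb$dX3
  }
  g
}

#' Forward pass of the seizure classifier
#'
#' Maps a batch of standardized windows to per-window seizure probabilities.
#' Inference is deterministic; dropout is active only when `training = TRUE`
#' (in which case masks are drawn from the current RNG stream).
#'
#' @param weights A `cnn_weights` object (see [init_cnn_weights] via
#'   [train_seizure_cnn()] or [cnn_spec()]).
#' @param x Numeric matrix, one window per row, `input_length` columns; a
#'   single window may be given as a vector.
#' @param training Logical; enable dropout.
#' @return Numeric vector of probabilities in (0, 1), one per window.
#' @export
cnn_forward <- function(weights, x, training = FALSE) {
  spec <- attr(weights, "spec")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  assert_that(ncol(x) == spec$input_length,
              paste0("windows must have length ", spec$input_length))
  cnn_forward_cache(weights, x, spec, training = training)$p
}

#' Thresholded seizure verdicts
#'
#' @inheritParams cnn_forward
#' @param threshold Decision threshold; a window is called seizure when its
#'   probability is greater than or equal to the threshold (ties favour
#'   sensitivity).
#' @return Integer vector of 0/1 verdicts.
#' @export
cnn_predict <- function(weights, x, threshold = NULL) {
  spec <- attr(weights, "spec")
  threshold <- threshold %||% spec$threshold
  as.integer(cnn_forward(weights, x) >= threshold)
}
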