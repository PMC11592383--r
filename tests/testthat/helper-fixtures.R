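# Shared fixtures, built once per test run and cached. Problem sizes are
# scaled down from the clinical protocol; the synthetic generator defaults
# are the study conditions and are never varied here.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fx_uci <- function(n_per_class = 200, seed = 5) {
  memo(paste0("uci_", n_per_class, "_", seed),
       gen_uci_like(n_per_class, synthetic_spec(seed = seed)))
}

# Desk-scale training protocol: single holdout validation split, small
# batches so the optimizer gets enough updates per epoch on a small set.
fx_train_config <- function(seed = 1) {
  train_config(n_folds = 1, max_epochs = 25, patience = 10,
               batch_size = 64, seed = seed)
}

fx_model <- function(seed = 1) {
  memo(paste0("model_", seed),
       train_seizure_cnn(fx_uci(), fx_train_config(seed)))
}

# Detection-grade model: trained on a larger window set so the per-cell
# false-alarm rate is low enough for clean site-by-second grids.
fx_detect_model <- function() {
  memo("model_detect", {
    cfg <- train_config(n_folds = 1, max_epochs = 30, patience = 10,
                        batch_size = 64, seed = 1)
    train_seizure_cnn(fx_uci(400, seed = 5), cfg)
  })
}

# Focal right-frontal onset ({F8, F4}) with later bilateral spread,
# mirroring a focal right-hemisphere seizure narrative.
fx_focal_schedule <- function(total = 40) {
  propagation_schedule(
    sites  = c("F8", "F4", "T4", "C4", "P4", "Fp2", "F3", "C3", "T3", "O1"),
    onset  = c(10, 10, 13, 14, 15, 15, 17, 18, 18, 19),
    offset = c(30, 29, 28, 28, 27, 27, 26, 25, 25, 24),
    total_duration = total
  )
}

# Straight-line forward pass of a small convolutional stack, written with
# nested loops only; the independent oracle for the vectorized model.
naive_forward <- function(weights, x, spec) {
  k <- spec$kernel_length; K <- spec$kernels_per_layer
  out <- numeric(nrow(x))
  for (n in seq_len(nrow(x))) {
    a <- matrix(x[n, ], ncol = 1)
    for (layer in seq_len(spec$n_conv_layers)) {
      W <- weights[[paste0("W", layer)]]
      b <- weights[[paste0("b", layer)]]
      C <- nrow(W) / k
      Lo <- nrow(a) - k + 1
      z <- matrix(0, Lo, K)
      for (pos in seq_len(Lo)) {
        for (kk in seq_len(K)) {
          acc <- b[kk]
          for (t in seq_len(k)) {
            for (c in seq_len(C)) {
              acc <- acc + a[pos + t - 1, c] * W[(t - 1) * C + c, kk]
            }
          }
          z[pos, kk] <- acc
        }
      }
      a <- pmax(z, 0)
    }
    Lp <- floor(nrow(a) / spec$pool_size)
    pooled <- matrix(0, Lp, K)
    for (i in seq_len(Lp)) {
      for (kk in seq_len(K)) {
        pooled[i, kk] <- max(a[((i - 1) * spec$pool_size + 1):(i * spec$pool_size), kk])
      }
    }
    flat <- numeric(Lp * K)
    for (i in seq_len(Lp)) for (kk in seq_len(K)) flat[(i - 1) * K + kk] <- pooled[i, kk]
    hidden <- pmax(as.vector(flat %*% weights$Wd) + weights$bd, 0)
    out[n] <- 1 / (1 + exp(-(sum(hidden * weights$Wo) + weights$bo)))
  }
  out
}
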