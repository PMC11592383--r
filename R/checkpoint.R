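#' Save a trained classifier checkpoint
#'
#' Writes a single JSON archive holding the architecture, every weight
#' array with its shape, the preprocessing configuration and the decision
#' threshold, so detection can reproduce training-time preprocessing
#' exactly.
#'
#' @param model A `seizure_cnn` (or a bare `cnn_weights` object).
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "cnn_weights")) {
    model <- structure(list(weights = model, spec = attr(model, "spec"),
                            preprocess = preprocess_config(),
                            config = NULL),
                       class = "seizure_cnn")
  }
  assert_that(inherits(model, "seizure_cnn"), "`model` must be a seizure_cnn")
  w <- model$weights
  payload <- list(
    format = "sozdetect-checkpoint-1",
    spec = unclass(model$spec)[setdiff(names(model$spec), "shapes")],
    preprocess = unclass(model$preprocess),
    threshold = model$spec$threshold,
    weights = lapply(unclass(w), function(p) {
      list(dim = if (is.null(dim(p))) length(p) else dim(p),
           data = as.vector(p))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return A `seizure_cnn` object (without training history).
#' @export
load_checkpoint <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(identical(payload$format, "sozdetect-checkpoint-1"),
              "not a recognized checkpoint file")
  spec <- do.call(cnn_spec, payload$spec)
  weights <- lapply(payload$weights, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  weights <- structure(weights, spec = spec, class = "cnn_weights")
  pp <- do.call(preprocess_config, payload$preprocess)
  structure(
    list(weights = weights, spec = spec, config = NULL, preprocess = pp,
         folds = NULL, best_fold = NA_integer_, test_metrics = NULL,
         history = NULL),
    class = "seizure_cnn"
  )
}
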