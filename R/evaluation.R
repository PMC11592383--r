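#' Confusion counts for binary seizure detection
#'
#' TP: detected seizure, labeled seizure. TN: detected non-seizure, labeled
#' non-seizure. FP: detected seizure, labeled non-seizure. FN: detected
#' non-seizure, labeled seizure.
#'
#' @param predictions Integer/logical vector of 0/1 verdicts.
#' @param truths Integer/logical vector of 0/1 labels, same length.
#' @return An object of class `confusion_counts` with elements `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion <- function(predictions, truths) {
  assert_that(length(predictions) > 0, "empty input")
  assert_that(length(predictions) == length(truths),
              "predictions and truths must have equal length")
  p <- as.integer(predictions); t_ <- as.integer(truths)
  assert_that(all(p %in% c(0L, 1L)) && all(t_ %in% c(0L, 1L)),
              "predictions and truths must be binary (0/1)")
  structure(
    list(tp = sum(p == 1L & t_ == 1L), tn = sum(p == 0L & t_ == 0L),
         fp = sum(p == 1L & t_ == 0L), fn = sum(p == 0L & t_ == 1L)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Accuracy, sensitivity and specificity in percent
#'
#' Accuracy = (TP + TN) / (TP + FN + TN + FP) x 100,
#' Sensitivity = TP / (TP + FN) x 100 (true-positive rate on seizure
#' windows), Specificity = TN / (TN + FP) x 100 (true-negative rate on
#' non-seizure windows).
#'
#' @param counts A [confusion()] object, or a 0/1 prediction vector (in which
#'   case `truths` must be supplied).
#' @param truths Optional 0/1 label vector.
#' @return A one-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity` (percent, full precision).
#' @export
#' @examples
#' seizure_metrics(confusion(c(1, 1, 0, 0), c(1, 0, 0, 1)))
seizure_metrics <- function(counts, truths = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- confusion(counts, truths)
  }
  pos <- counts$tp + counts$fn
  neg <- counts$tn + counts$fp
  assert_that(pos > 0, "sensitivity undefined: no positive (seizure) samples")
  assert_that(neg > 0, "specificity undefined: no negative (non-seizure) samples")
  tibble::tibble(
    accuracy = (counts$tp + counts$tn) / (pos + neg) * 100,
    sensitivity = counts$tp / pos * 100,
    specificity = counts$tn / neg * 100
  )
}
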