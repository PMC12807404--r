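#' Area under the ROC curve
#'
#' Computed from the Mann-Whitney rank statistic over the probabilities
#' (ties share mid-ranks), equivalent to the probability that a random
#' impaired case scores above a random control.
#'
#' @param y_true Integer 0/1 truth.
#' @param y_prob Scores/probabilities.
#' @return AUROC in `[0, 1]`; errors if only one class is present.
#' @export
auroc <- function(y_true, y_prob) {
  stopifnot(length(y_true) == length(y_prob))
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) abort("AUROC is undefined with a single class")
  r <- rank(y_prob)
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics
#'
#' Confusion-matrix metrics at a probability threshold plus rank-based
#' AUROC: accuracy, F1 (harmonic mean of precision and sensitivity),
#' precision, sensitivity (recall), specificity, AUROC. When only one class
#' is present in the truth, AUROC is `NA` with a warning; the threshold
#' metrics are still computed.
#'
#' @param y_true Integer 0/1 truth.
#' @param y_prob Predicted probabilities.
#' @param threshold Decision threshold (default 0.5; predicted impaired
#'   when probability > threshold).
#' @return One-row tibble of the six metrics, with the confusion counts
#'   (`tp`, `fp`, `tn`, `fn`) as the `"confusion"` attribute.
#' @export
compute_metrics <- function(y_true, y_prob, threshold = 0.5) {
  stopifnot(length(y_true) == length(y_prob), all(y_true %in% 0:1))
  y_hat <- as.integer(y_prob > threshold)
  tp <- sum(y_hat == 1 & y_true == 1)
  fp <- sum(y_hat == 1 & y_true == 0)
  tn <- sum(y_hat == 0 & y_true == 0)
  fn <- sum(y_hat == 0 & y_true == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else 0
  specificity <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (precision + sensitivity > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else 0
  auc <- if (length(unique(y_true)) < 2) {
    warn("compute_metrics: single-class truth; AUROC is NA")
    NA_real_
  } else {
    auroc(y_true, y_prob)
  }
  out <- tibble::tibble(
    accuracy = (tp + tn) / length(y_true),
    f1 = f1, precision = precision, sensitivity = sensitivity,
    specificity = specificity, auroc = auc
  )
  attr(out, "confusion") <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  out
}
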