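# Evaluation metrics at a fixed operating point plus threshold-free AUC.

#' Evaluate classifier scores against binary labels
#'
#' The confusion matrix is taken at `threshold` (score >= threshold =>
#' predicted positive). AUC is the probability of concordance between a
#' random positive/negative pair, with ties counted 1/2 (computed via
#' mid-ranks; equivalent to the pairwise concordance estimator). Metrics
#' whose denominator class is absent are reported as NA, not 0.
#'
#' @param scores positive-class probabilities in [0,1].
#' @param labels binary labels (1 = positive).
#' @param threshold decision threshold, default 0.5.
#' @return a `lus_metrics` list: sensitivity, specificity, accuracy, auc,
#'   threshold, confusion (named TP/FN/FP/TN integer vector), n.
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop_taaft("scores and labels must have the same length",
               class = "taaft_validation_error")
  }
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  n1 <- tp + fn; n0 <- fp + tn
  structure(list(
    sensitivity = if (n1 > 0) tp / n1 else NA_real_,
    specificity = if (n0 > 0) tn / n0 else NA_real_,
    accuracy = if (n1 + n0 > 0) (tp + tn) / (n1 + n0) else NA_real_,
    auc = auc_score(scores, labels),
    threshold = threshold,
    confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
    n = n1 + n0
  ), class = "lus_metrics")
}

#' Concordance AUC
#'
#' Mid-rank formulation of the pairwise concordance estimator: ties count
#' 1/2. NA when either class is absent.
#' @inheritParams evaluate
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)  # mid-ranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.lus_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf(
    "<lus_metrics> n=%d  sens=%s  spec=%s  auc=%s  acc=%s (thr=%.2f)\n",
    x$n, fmt(x$sensitivity), fmt(x$specificity), fmt(x$auc),
    fmt(x$accuracy), x$threshold))
  print(x$confusion)
  invisible(x)
}
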