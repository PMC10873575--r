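# Imbalance-aware evaluation metrics.

#' Confusion counts and classification metrics
#'
#' Thresholds the scores, tabulates the confusion matrix and computes
#' accuracy, precision, recall and F1 from the counts, plus two
#' threshold-free summaries: AUROC as the Mann-Whitney rank statistic with
#' midranks for ties, and AUPRC as average precision (step integration of
#' the precision-recall curve over the score ranking).
#'
#' @param p numeric scores (probability of the positive class).
#' @param labels 0/1 labels of equal length.
#' @param threshold score cut for the confusion matrix (default 0.5; class 1
#'   is called when `p >= threshold`).
#' @return a `metric_report` list with `TP`, `TN`, `FP`, `FN`, `ACC`,
#'   `Precision`, `Recall`, `F1`, `AUPRC`, `AUROC`. Degenerate inputs (a
#'   single class present) yield 0 for the undefined metrics together with a
#'   `degenerate` flag and a warning.
#' @examples
#' confusion_and_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$AUROC
#' @export
confusion_and_metrics <- function(p, labels, threshold = 0.5) {
  if (length(p) != length(labels)) stop("p and labels must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  pred <- as.integer(p >= threshold)
  TP <- sum(pred == 1L & labels == 1)
  TN <- sum(pred == 0L & labels == 0)
  FP <- sum(pred == 1L & labels == 0)
  FN <- sum(pred == 0L & labels == 1)
  degenerate <- FALSE
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    warning("only one class present; rank metrics and recall/precision degenerate")
    degenerate <- TRUE
  }
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(
    TP = TP, TN = TN, FP = FP, FN = FN,
    ACC = (TP + TN) / length(labels),
    Precision = precision, Recall = recall, F1 = f1,
    AUPRC = if (degenerate) 0 else average_precision(p, labels),
    AUROC = if (degenerate) 0 else auroc_rank(p, labels),
    degenerate = degenerate
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("confusion: TP=%d TN=%d FP=%d FN=%d\n", x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("ACC=%.4f  Precision=%.4f  Recall=%.4f  F1=%.4f\n",
              x$ACC, x$Precision, x$Recall, x$F1))
  cat(sprintf("AUPRC=%.4f  AUROC=%.4f\n", x$AUPRC, x$AUROC))
  invisible(x)
}

# AUROC via the Mann-Whitney U statistic with midranks for tied scores.
auroc_rank <- function(p, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(p, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision: step integration of the precision-recall curve,
# sum_k (R_k - R_{k-1}) * P_k over distinct score thresholds in decreasing
# order. Tied scores are grouped into one threshold, so the value does not
# depend on any intra-tie ordering.
average_precision <- function(p, labels) {
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]; lab <- labels[ord]
  last <- cumsum(rle(ps)$lengths)   # last index of each tie group
  tp_k <- cumsum(lab)[last]
  prec_k <- tp_k / last
  sum(prec_k * diff(c(0, tp_k))) / sum(lab)
}

#' Serialize a metric report to JSON
#'
#' @param report a `metric_report` from [confusion_and_metrics()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  keys <- c("ACC", "AUPRC", "AUROC", "Precision", "Recall", "F1",
            "TP", "TN", "FP", "FN")
  jsonlite::write_json(report[keys], path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
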