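# Evaluation metrics for imbalanced per-residue binary classification.

#' Area under the ROC curve (rank-sum form)
#'
#' Computed from the Mann-Whitney statistic with midranks, so ties are
#' handled exactly.
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector of positive-class scores.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length", call. = FALSE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0L || nn == 0L)
    stop("AUROC undefined: labels contain a single class", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (step-wise summation)
#'
#' Precision is interpolated step-wise over the distinct score thresholds in
#' decreasing order; the area is `sum(delta recall * precision)` (the average
#' -precision convention).
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length", call. = FALSE)
  P <- sum(labels == 1)
  if (P == 0L || P == length(labels))
    stop("AUPRC undefined: labels contain a single class", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each threshold
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / P
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

safe_div <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s has zero denominator; returning 0", what), call. = FALSE)
    0
  } else num / den
}

#' Confusion-count metrics
#'
#' Closed-form accuracy, precision, recall, F1 and Matthews correlation from
#' the four confusion counts. Degenerate denominators yield 0 with a warning.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return one-row tibble with `ACC`, `Precision`, `Recall`, `F1`, `MCC`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    warning("MCC has zero denominator; returning 0", call. = FALSE); 0
  } else (tp * tn - fp * fn) / mcc_den
  tibble::tibble(ACC = safe_div(tp + tn, n, "accuracy"),
                 Precision = precision, Recall = recall, F1 = f1, MCC = mcc)
}

#' Evaluate per-residue predictions
#'
#' Thresholds the scores, derives the confusion counts and closed-form
#' metrics, and adds rank-based AUROC and step-wise AUPRC. When the labels
#' contain a single class the two ranking metrics are `NA` with a warning;
#' the threshold metrics are still reported.
#'
#' @param labels 0/1 vector.
#' @param scores positive-class probability vector.
#' @param threshold decision threshold for binary calls (default 0.5).
#' @return one-row tibble: `ACC`, `Precision`, `Recall`, `F1`, `MCC`,
#'   `AUROC`, `AUPRC`, `TP`, `TN`, `FP`, `FN`.
#' @export
#' @examples
#' evaluate(c(0, 0, 1, 1), c(.1, .4, .6, .9))
evaluate <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length", call. = FALSE)
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  calls <- as.integer(scores >= threshold)
  tp <- sum(calls == 1 & labels == 1); tn <- sum(calls == 0 & labels == 0)
  fp <- sum(calls == 1 & labels == 0); fn <- sum(calls == 0 & labels == 1)
  cm <- confusion_metrics(tp, tn, fp, fn)
  roc <- tryCatch(auroc(labels, scores), error = function(e) {
    warning(conditionMessage(e), call. = FALSE); NA_real_
  })
  prc <- tryCatch(auprc(labels, scores), error = function(e) {
    warning(conditionMessage(e), call. = FALSE); NA_real_
  })
  dplyr::mutate(cm, AUROC = roc, AUPRC = prc,
                TP = tp, TN = tn, FP = fp, FN = fn)
}
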