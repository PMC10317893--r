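# Confusion-matrix metrics and rank-based AUC.

#' Confusion-matrix metrics for binary predictions
#'
#' Positive predictive value and negative predictive value are reported as
#' `NA` when their denominator (predicted positives / negatives) is zero.
#'
#' @param predicted 0/1 predicted classes.
#' @param truth 0/1 observed endpoint.
#' @param risks Optional numeric risk scores; when supplied and both
#'   classes are present, the rank-based AUC is included.
#' @return A `tg_metrics` list: `tp`, `fp`, `tn`, `fn`, `accuracy`, `ppv`,
#'   `npv`, `sensitivity`, `specificity`, `prevalence`, `auc`.
#' @export
confusion_metrics <- function(predicted, truth, risks = NULL) {
  if (length(predicted) == 0L) stop("empty input")
  if (length(predicted) != length(truth)) stop("length mismatch")
  stopifnot(all(predicted %in% 0:1), all(truth %in% 0:1))
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  tn <- sum(predicted == 0 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  n <- tp + fp + tn + fn
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / n,
    ppv = rat(tp, tp + fp),
    npv = rat(tn, tn + fn),
    sensitivity = rat(tp, tp + fn),
    specificity = rat(tn, tn + fp),
    prevalence = (tp + fn) / n,
    auc = if (is.null(risks)) NA_real_ else auc_score(risks, truth)
  ), class = "tg_metrics")
}

#' Rank-based AUC (concordance with midrank ties)
#'
#' Computes the Mann-Whitney version of the area under the ROC curve:
#' the probability that a random event outranks a random non-event, with
#' ties counted 1/2 (midranks).
#'
#' @param risks Numeric scores (higher = more likely event).
#' @param truth 0/1 observed endpoint.
#' @return AUC in [0, 1], or `NA` if only one class is present.
#' @export
auc_score <- function(risks, truth) {
  stopifnot(length(risks) == length(truth), all(truth %in% 0:1))
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(risks, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.tg_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("confusion: TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  fmt <- function(v) if (is.na(v)) "NA" else formatC(v, digits = digits, format = "f")
  cat(sprintf("accuracy %s  PPV %s  NPV %s  sens %s  spec %s  AUC %s\n",
              fmt(x$accuracy), fmt(x$ppv), fmt(x$npv), fmt(x$sensitivity),
              fmt(x$specificity), fmt(x$auc)))
  invisible(x)
}
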