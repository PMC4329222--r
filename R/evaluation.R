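# Contingency-table metrics and ROC/AUC.

#' Build a 2x2 contingency table
#'
#' Positive = nodule present. Cell counts always sum to the sequence
#' length.
#'
#' @param predicted,truth Equal-length binary 0/1 vectors.
#' @return Object of class `contingency_table` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
contingency <- function(predicted, truth) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (length(predicted) != length(truth) || length(truth) < 1L) {
    stopf("`predicted` and `truth` must be equal-length, non-empty")
  }
  if (!all(c(predicted, truth) %in% c(0L, 1L))) {
    stopf("inputs must be binary 0/1")
  }
  structure(list(TP = sum(predicted == 1L & truth == 1L),
                 FP = sum(predicted == 1L & truth == 0L),
                 TN = sum(predicted == 0L & truth == 0L),
                 FN = sum(predicted == 0L & truth == 1L)),
            class = "contingency_table")
}

#' Construct a contingency table from counts
#'
#' @param TP,FP,TN,FN Non-negative integer counts (total >= 1).
#' @return A `contingency_table`.
#' @export
contingency_table <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts)) || sum(counts) < 1) {
    stopf("counts must be non-negative integers with total >= 1")
  }
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 TN = as.integer(TN), FN = as.integer(FN)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}

#' Sensitivity, specificity and preciseness of a contingency table
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `preciseness = (TP + TN) / total` (i.e. overall accuracy), all returned
#' as percentages. A zero denominator yields `NA` with the metric listed in
#' the `undefined` field rather than propagating NaN.
#'
#' @param tab A `contingency_table`.
#' @return List with `sensitivity`, `specificity`, `preciseness` (percent)
#'   and `undefined` (character vector of metrics with empty denominators).
#' @examples
#' cadx_metrics(contingency_table(TP = 20, FP = 6, TN = 17, FN = 2))
#' @export
cadx_metrics <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(NA_real_)
    }
    100 * num / den
  }
  out <- list(
    sensitivity = ratio(tab$TP, tab$TP + tab$FN, "sensitivity"),
    specificity = ratio(tab$TN, tab$TN + tab$FP, "specificity"),
    preciseness = ratio(tab$TP + tab$TN, tab$TP + tab$FP + tab$TN + tab$FN,
                        "preciseness"))
  out$undefined <- undefined
  out
}

#' ROC curve and AUC from decision scores
#'
#' Thresholds are placed at every distinct score (tied scores cross the
#' threshold simultaneously); the AUC is the trapezoidal area, which equals
#' the Mann-Whitney pair statistic with ties counted 1/2.
#'
#' @param scores Real decision scores (higher = more nodule-like).
#' @param truth Binary 0/1 truth; both classes must be present.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`,
#'   starting at (0, 0) and ending at (1, 1)) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth)) stopf("length mismatch")
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stopf("both classes must be present for a ROC curve")
  }
  ord <- order(-scores)
  s <- scores[ord]; y <- truth[ord]
  distinct <- !duplicated(s)
  cum_tp <- cumsum(y == 1L); cum_fp <- cumsum(y == 0L)
  # last index of each tied block = counts after the whole block crosses
  block_end <- c(which(distinct)[-1] - 1L, length(s))
  tpr <- c(0, cum_tp[block_end] / n_pos)
  fpr <- c(0, cum_fp[block_end] / n_neg)
  thr <- c(Inf, s[distinct])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}
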