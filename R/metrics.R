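#' Confusion counts at the clonotype level
#'
#' @param calls Named logical/character vector of predicted calls per
#'   clonotype (\code{TRUE}/\code{"reactive"} = positive).
#' @param truth Named vector of experimental reactivity over the same
#'   clonotype ids.
#' @return List of class \code{confusion_counts} with \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}.
#' @export
confusion <- function(calls, truth) {
  to_bin <- function(v) {
    if (is.character(v)) v == "reactive" else as.logical(v)
  }
  if (is.null(names(calls)) || is.null(names(truth)) ||
      !setequal(names(calls), names(truth)))
    stop_validation("calls and truth must cover the same clonotype ids")
  truth <- truth[names(calls)]
  p <- to_bin(calls); t <- to_bin(truth)
  confusion_counts(tp = sum(p & t), fp = sum(p & !t),
                   tn = sum(!p & !t), fn = sum(!p & t))
}

#' Construct confusion counts directly
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return \code{confusion_counts} object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v)))
    stop_validation("confusion counts must be non-negative integers")
  if (sum(v) < 1) stop_validation("confusion counts are all zero")
  structure(as.list(v), class = "confusion_counts")
}

#' Classification accuracy
#'
#' @param c \code{confusion_counts}.
#' @return (tp + tn) / (tp + fp + tn + fn).
#' @export
accuracy <- function(c) {
  (c$tp + c$tn) / (c$tp + c$fp + c$tn + c$fn)
}

#' Geometric mean of sensitivity and specificity
#'
#' The preferred summary for imbalanced clonotype validation sets:
#' \eqn{\sqrt{\mathrm{TPR} \times \mathrm{TNR}}}. Undefined (NA) when either
#' class is absent from the truth, mirroring how published per-sample tables
#' report it.
#'
#' @param c \code{confusion_counts}.
#' @return G-mean in [0, 1], or \code{NA} if a truth class is empty.
#' @export
g_mean <- function(c) {
  pos <- c$tp + c$fn
  neg <- c$tn + c$fp
  if (pos == 0 || neg == 0) return(NA_real_)
  sqrt((c$tp / pos) * (c$tn / neg))
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney statistic: the fraction of
#' (positive, negative) clonotype pairs where the positive scores higher,
#' with half credit for ties (equivalent to rank-based computation).
#'
#' @param scores Numeric scores per clonotype.
#' @param truth Logical (or \code{"reactive"}-coded character) truth of the
#'   same length.
#' @return AUC in [0, 1]; \code{NA} if only one class is present.
#' @export
roc_auc <- function(scores, truth) {
  t <- if (is.character(truth)) truth == "reactive" else as.logical(truth)
  n1 <- sum(t); n0 <- sum(!t)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[t]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Metric report for one validation sample
#'
#' @param calls,truth As in [confusion()].
#' @param scores Optional numeric scores (for AUC), named like
#'   \code{calls}.
#' @return List with confusion counts and accuracy / G-mean / AUC, each
#'   additionally rounded half-up to 2 decimals in \code{*_2dp} fields.
#' @export
evaluate_calls <- function(calls, truth, scores = NULL) {
  cc <- confusion(calls, truth)
  auc <- if (is.null(scores)) NA_real_ else
    roc_auc(scores[names(calls)], truth[names(calls)])
  res <- list(confusion = cc, accuracy = accuracy(cc), g_mean = g_mean(cc),
              auc = auc)
  res$accuracy_2dp <- round_half_up(res$accuracy)
  res$g_mean_2dp <- if (is.na(res$g_mean)) NA_real_ else
    round_half_up(res$g_mean)
  res
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts: TP", x$tp, " FP", x$fp, " TN", x$tn, " FN", x$fn,
      "\n")
  invisible(x)
}
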