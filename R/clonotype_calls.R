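#' Aggregate per-cell probabilities to per-clonotype scores
#'
#' Cells of one TCR clonotype can occupy diverse phenotypic states, so the
#' clonotype reactivity score is the arithmetic mean of its cells'
#' predicted probabilities.
#'
#' @param cell_probs Named numeric vector of per-cell probabilities (names
#'   are barcodes).
#' @param clonotypes Clonotype table (columns \code{barcode},
#'   \code{clonotype_id}).
#' @param min_cells Clonotypes with fewer cells than this are dropped
#'   (default 1: singletons are scored).
#' @return data.frame with \code{clonotype_id}, \code{n_cells},
#'   \code{mean_probability}, sorted by clonotype id.
#' @export
score_clonotypes <- function(cell_probs, clonotypes, min_cells = 1) {
  cells <- unique(clonotypes[, c("barcode", "clonotype_id")])
  cells <- cells[cells$barcode %in% names(cell_probs), , drop = FALSE]
  if (!nrow(cells))
    stop_validation("no overlap between scored barcodes and clonotype table")
  sp <- split(cell_probs[cells$barcode], cells$clonotype_id)
  out <- data.frame(clonotype_id = names(sp),
                    n_cells = lengths(sp),
                    mean_probability = vapply(sp, mean, numeric(1)),
                    stringsAsFactors = FALSE)
  out <- out[out$n_cells >= min_cells, , drop = FALSE]
  out <- out[order(out$clonotype_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher-Jenks natural-break threshold
#'
#' Exact dynamic-programming partition of sorted values into
#' \code{n_classes} contiguous classes minimizing the total within-class sum
#' of squared deviations (the 1-D analogue of k-means, solved exactly). The
#' returned threshold is the minimum value of the top class — the minimum
#' score required to be called reactive.
#'
#' @param values Numeric vector with at least \code{n_classes} distinct
#'   values.
#' @param n_classes Number of classes (default 2).
#' @return Numeric threshold, with attribute \code{breaks} (lower bound of
#'   each class) and \code{ssd} (optimal total within-class SSD).
#' @export
fisher_jenks_threshold <- function(values, n_classes = 2) {
  x <- sort(as.numeric(values))
  n <- length(x)
  k <- as.integer(n_classes)
  if (k < 2) stop_validation("n_classes must be >= 2")
  if (length(unique(x)) < k)
    stop_validation("degenerate distribution: fewer than ", k,
                    " distinct values")
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  # ssd of x[(i+1)..j] from prefix sums
  seg <- function(i, j) {
    s <- cs[j] - if (i > 0) cs[i] else 0
    s2 <- cs2[j] - if (i > 0) cs2[i] else 0
    s2 - s^2 / (j - i)
  }
  # dp[c, j]: minimal SSD of first j values in c classes
  dp <- matrix(Inf, k, n)
  idx <- matrix(0L, k, n)
  for (j in 1:n) dp[1, j] <- seg(0, j)
  for (c in 2:k) {
    for (j in c:n) {
      best <- Inf; bi <- 0L
      for (i in (c - 1):(j - 1)) {
        v <- dp[c - 1, i] + seg(i, j)
        # <= prefers the latest feasible split, pushing boundary ties into
        # the upper class
        if (v <= best) { best <- v; bi <- i }
      }
      dp[c, j] <- best; idx[c, j] <- bi
    }
  }
  # backtrack class lower bounds
  bounds <- numeric(k)
  j <- n
  for (c in k:1) {
    i <- if (c > 1) idx[c, j] else 0L
    bounds[c] <- x[i + 1]
    j <- i
  }
  structure(bounds[k], breaks = bounds, ssd = dp[k, n])
}

#' Call reactive clonotypes with a sample-specific threshold
#'
#' The decision threshold is computed on the sample's own score vector by
#' Fisher-Jenks natural-break optimization — a deterministic rule that
#' adapts to each sample's score distribution. A clonotype is called
#' reactive when its mean probability is at or above the threshold
#' (the threshold is itself the lowest reactive score).
#'
#' @param scores data.frame from [score_clonotypes()] (or any frame with
#'   \code{clonotype_id} and \code{mean_probability}).
#' @return The input with \code{threshold} and \code{call}
#'   (\code{"reactive"}/\code{"nonreactive"}) columns appended.
#' @export
call_reactive <- function(scores) {
  thr <- fisher_jenks_threshold(scores$mean_probability)
  scores$threshold <- as.numeric(thr)
  scores$call <- ifelse(scores$mean_probability >= as.numeric(thr),
                        "reactive", "nonreactive")
  scores
}

#' Keep only clonotypes above a score percentile
#'
#' For manufacturing prioritization: restricting to clonotypes whose mean
#' probability lies strictly above the \code{q}-th empirical percentile
#' (linear-interpolation definition) trades recall for a lower false
#' positive rate.
#'
#' @param scores data.frame with \code{mean_probability}.
#' @param q Percentile in (0, 1); default 0.95.
#' @return Subset of \code{scores}, ranked by descending mean probability.
#' @export
percentile_filter <- function(scores, q = 0.95) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1)
    stop_validation("q must lie strictly between 0 and 1")
  if (!nrow(scores)) stop_validation("no scores supplied")
  cut <- quantile(scores$mean_probability, q, type = 7, names = FALSE)
  out <- scores[scores$mean_probability > cut, , drop = FALSE]
  out[order(-out$mean_probability, out$clonotype_id), , drop = FALSE]
}
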