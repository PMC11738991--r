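# Four published per-cell gene-signature baselines, all funneled through
# the same clonotype aggregation + Fisher-Jenks calling layer as the
# classifier, so method comparisons differ only in the per-cell score.

# per-cell ranks, largest expression = rank 1, ties average
rank_desc <- function(v) rank(-v, ties.method = "average")

#' Single-sample gene-set enrichment score per cell
#'
#' ssGSEA-style running-sum statistic: for each cell, genes are ordered by
#' decreasing expression (ties by average rank). Walking down the list, the
#' hit curve accumulates signature genes weighted by (N - position + 1)
#' raised to \code{alpha} (0.25, the ssGSEA convention), the miss curve
#' accumulates non-signature genes uniformly; the score is the mean of
#' (hit - miss) over all list positions, positive when signature genes
#' concentrate at the top. Rank-based, hence invariant to any strictly
#' monotone transform of a cell's expression vector — raw counts are a
#' valid input.
#'
#' @param m count matrix (raw counts) or any genes x cells expression
#'   matrix.
#' @param sig A [gene_signature()] (positive genes only are used).
#' @param alpha Rank-weight exponent (default 0.25).
#' @return data.frame \code{barcode}, \code{score}.
#' @export
score_ssgsea <- function(m, sig, alpha = 0.25) {
  genes <- rownames(m)
  in_set <- genes %in% sig$positive
  if (!any(in_set))
    stop_validation("no signature genes present in the matrix")
  N <- length(genes)
  n_miss <- N - sum(in_set)
  x <- as.matrix(m)
  score <- vapply(seq_len(ncol(x)), function(c) {
    r <- rank_desc(x[, c])
    ord <- order(r)
    hit <- in_set[ord]
    w <- (N - r[ord] + 1)^alpha * hit
    p_hit <- cumsum(w) / sum(w)
    p_miss <- cumsum(!hit) / n_miss
    mean(p_hit - p_miss)
  }, numeric(1))
  data.frame(barcode = colnames(m), score = score,
             stringsAsFactors = FALSE)
}

#' Flag reactive cells from cluster-level enrichment
#'
#' Clusters whose mean signature score reaches the 0.95 quantile of the
#' cluster-mean distribution are designated reactive; every member cell of
#' such a cluster is flagged. Cluster labels come from an external
#' clustering step; ties at the quantile are flagged.
#'
#' @param scores data.frame from [score_ssgsea()].
#' @param clusters Named vector (names = barcodes) of cluster labels.
#' @param q Quantile the cluster mean must reach (default 0.95).
#' @return The input with a logical \code{reactive_flag} column.
#' @export
neotcr8_reactive_cells <- function(scores, clusters, q = 0.95) {
  if (is.null(names(clusters)) ||
      !all(scores$barcode %in% names(clusters)))
    stop_validation("cluster labels missing for some barcodes")
  cl <- clusters[scores$barcode]
  cl_mean <- tapply(scores$score, cl, mean)
  cut <- quantile(cl_mean, q, type = 7, names = FALSE)
  hot <- names(cl_mean)[cl_mean >= cut]
  scores$reactive_flag <- cl %in% hot
  scores
}

#' Reactive-cell-fraction score per clonotype
#'
#' @param scores data.frame with \code{barcode} and \code{reactive_flag}
#'   (from [neotcr8_reactive_cells()]).
#' @param clonotypes Clonotype table.
#' @param min_cells Minimum cells per scored clonotype.
#' @return data.frame \code{clonotype_id}, \code{n_cells},
#'   \code{mean_probability} (= flagged / total cells).
#' @export
neotcr8_clonotype_score <- function(scores, clonotypes, min_cells = 1) {
  flags <- setNames(as.numeric(scores$reactive_flag), scores$barcode)
  score_clonotypes(flags, clonotypes, min_cells = min_cells)
}

#' Additive signature score
#'
#' Sum of expression over positively contributing genes minus the sum over
#' negatively contributing genes, on log-normalized expression; a cell is
#' signature-positive when the score is strictly positive.
#'
#' @param norm Log-normalized genes x cells matrix (see
#'   [log_normalize()]).
#' @param sig A [gene_signature()].
#' @return data.frame \code{barcode}, \code{score}, \code{reactive_flag}.
#' @export
score_additive <- function(norm, sig) {
  pos <- intersect(sig$positive, rownames(norm))
  if (!length(pos))
    stop_validation("no signature genes present in the matrix")
  neg <- intersect(sig$negative, rownames(norm))
  s <- colSums(norm[pos, , drop = FALSE])
  if (length(neg)) s <- s - colSums(norm[neg, , drop = FALSE])
  data.frame(barcode = colnames(norm), score = unname(s),
             reactive_flag = unname(s > 0), stringsAsFactors = FALSE)
}

#' Expression-bin-controlled module score
#'
#' Genes are binned into \code{n_bins} by average expression; for each
#' signature gene \code{n_ctrl} control genes are drawn from its bin
#' (without replacement when the bin allows, otherwise with replacement and
#' a warning). The score is the mean expression of the signature genes
#' minus the mean expression of the pooled control genes, per cell; a
#' signature matching its own background scores 0 in expectation.
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param sig A [gene_signature()] (positive genes only).
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes drawn per signature gene (default 100).
#' @param seed Integer seed for the control draw.
#' @return data.frame \code{barcode}, \code{score}, \code{reactive_flag}.
#' @export
score_module <- function(norm, sig, n_bins = 24, n_ctrl = 100, seed = 1) {
  genes <- rownames(norm)
  pos <- intersect(sig$positive, genes)
  if (!length(pos))
    stop_validation("no signature genes present in the matrix")
  avg <- rowMeans(norm)
  n_bins <- min(n_bins, length(genes))
  bin <- if (n_bins < 2) rep(1L, length(genes))
         else cut(rank(avg, ties.method = "first"), breaks = n_bins,
                  labels = FALSE)
  names(bin) <- genes
  ctrl <- with_seed(seed, {
    unlist(lapply(pos, function(g) {
      pool <- setdiff(genes[bin == bin[g]], pos)
      if (!length(pool)) pool <- setdiff(genes, pos)
      if (length(pool) >= n_ctrl) sample(pool, n_ctrl)
      else {
        warning("expression bin too small for ", n_ctrl,
                " controls; sampling with replacement")
        sample(pool, n_ctrl, replace = TRUE)
      }
    }))
  })
  sig_mean <- colMeans(norm[pos, , drop = FALSE])
  ctrl_mean <- colMeans(norm[ctrl, , drop = FALSE])
  s <- sig_mean - ctrl_mean
  data.frame(barcode = colnames(norm), score = unname(s),
             reactive_flag = unname(s > 0), stringsAsFactors = FALSE)
}

#' Rank-based (Mann-Whitney U) signature score
#'
#' Per cell, genes are ranked by decreasing expression with ties averaged
#' and ranks capped at \code{rank_cap}; with
#' \eqn{U = \sum ranks(signature) - n(n+1)/2} the score is
#' \eqn{1 - U / (n \cdot rank\_cap)}, clamped to [0, 1]: 1 when the
#' signature genes occupy the very top of the cell's profile, near 0 when
#' they all sit at or beyond the rank cap. Rank-based, so raw counts are a
#' valid input.
#'
#' @param m Expression matrix (genes x cells), typically raw counts.
#' @param sig A [gene_signature()] (positive genes only).
#' @param rank_cap Maximum informative rank (default 1500).
#' @return data.frame \code{barcode}, \code{score}.
#' @export
score_rank_u <- function(m, sig, rank_cap = 1500) {
  pos <- intersect(sig$positive, rownames(m))
  if (!length(pos))
    stop_validation("no signature genes present in the matrix")
  n_sig <- length(pos)
  x <- as.matrix(m)
  score <- vapply(seq_len(ncol(x)), function(c) {
    r <- pmin(rank_desc(x[, c]), rank_cap)
    u <- sum(r[match(pos, rownames(m))]) - n_sig * (n_sig + 1) / 2
    min(max(1 - u / (n_sig * rank_cap), 0), 1)
  }, numeric(1))
  data.frame(barcode = colnames(m), score = score,
             stringsAsFactors = FALSE)
}

#' Score cells with a signature using its declared method
#'
#' Dispatches to the appropriate scorer and normalization: rank-based
#' methods (\code{ssgsea}, \code{rank_u}) run on raw counts; \code{additive}
#' and \code{module} run on log-normalized expression.
#'
#' @param counts count matrix (raw).
#' @param sig A [gene_signature()].
#' @param seed Seed for the module-score control draw.
#' @return Per-cell score data.frame (method-dependent columns).
#' @export
score_signature <- function(counts, sig, seed = 1) {
  switch(sig$method,
         ssgsea = score_ssgsea(counts, sig),
         rank_u = score_rank_u(counts, sig),
         additive = score_additive(log_normalize(counts), sig),
         module = score_module(log_normalize(counts), sig, seed = seed),
         stop_validation("unknown signature method: ", sig$method))
}

#' Clonotype-level calls from per-cell signature scores
#'
#' Aggregates per-cell signature scores to clonotype means (or, for the
#' flag-ratio path used by cluster-based signatures, the fraction of
#' flagged cells) and applies the shared Fisher-Jenks thresholding layer.
#'
#' @param scores Per-cell score data.frame (\code{barcode} plus
#'   \code{score} and/or \code{reactive_flag}).
#' @param clonotypes Clonotype table.
#' @param use_flags If \code{TRUE}, aggregate \code{reactive_flag}
#'   fractions instead of mean scores.
#' @param min_cells Minimum cells per scored clonotype.
#' @return data.frame of clonotype scores with \code{threshold} and
#'   \code{call}.
#' @export
signature_clonotype_calls <- function(scores, clonotypes,
                                      use_flags = FALSE, min_cells = 1) {
  v <- if (use_flags) {
    if (is.null(scores$reactive_flag))
      stop_validation("scores carry no reactive_flag column")
    setNames(as.numeric(scores$reactive_flag), scores$barcode)
  } else setNames(scores$score, scores$barcode)
  call_reactive(score_clonotypes(v, clonotypes, min_cells = min_cells))
}
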