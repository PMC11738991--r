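#' Filter low-quality cells by total counts and detected features
#'
#' A cell is removed when its total RNA count falls below \code{min_total}
#' or its number of detected genes (count > 0) falls below
#' \code{min_features}. Both thresholds are strict (a cell at exactly the
#' threshold is retained). The defaults (1200 counts, 500 features) are the
#' cut-offs used for droplet-based TIL libraries; \code{rule = "and"}
#' switches to removing only cells failing both.
#'
#' @param m count matrix (genes x cells).
#' @param min_total Minimum total counts per cell.
#' @param min_features Minimum number of genes detected per cell.
#' @param rule \code{"or"} (default): fail either criterion and the cell is
#'   dropped; \code{"and"}: drop only if both fail.
#' @return Filtered count matrix (gene list unchanged).
#' @export
filter_cells <- function(m, min_total = 1200, min_features = 500,
                         rule = c("or", "and")) {
  rule <- match.arg(rule)
  totals <- Matrix::colSums(m)
  feats <- Matrix::colSums(m > 0)
  fail_total <- totals < min_total
  fail_feat <- feats < min_features
  drop <- if (rule == "or") fail_total | fail_feat else fail_total & fail_feat
  if (all(drop)) warning("all cells removed by QC filter")
  sid <- attr(m, "sample_id")
  out <- m[, !drop, drop = FALSE]
  attr(out, "sample_id") <- sid
  out
}

#' Restrict several count matrices to their common gene set
#'
#' Training pools TIL and multi-source healthy-donor data; matrices are
#' harmonized to the sorted intersection of their gene symbols so that all
#' cells share one feature space.
#'
#' @param matrices List of count matrices.
#' @param mask_vdj If \code{TRUE}, TCR V(D)J segment genes (TRAV/TRBV/...)
#'   are removed from the feature list, preventing the classifier from
#'   keying on clonotype identity itself. Off by default.
#' @return List with \code{features} (sorted common gene symbols) and
#'   \code{matrices} (inputs reindexed to that feature list).
#' @export
harmonize_genes <- function(matrices, mask_vdj = FALSE) {
  if (!length(matrices)) stop_validation("no matrices supplied")
  common <- rownames(matrices[[1]])
  for (m in matrices[-1]) common <- intersect(common, rownames(m))
  if (mask_vdj) common <- common[!is_vdj_gene(common)]
  if (!length(common))
    stop_validation("gene sets have an empty intersection")
  features <- sort(common)
  out <- lapply(matrices, function(m) {
    sid <- attr(m, "sample_id")
    r <- m[features, , drop = FALSE]
    attr(r, "sample_id") <- sid
    r
  })
  list(features = features, matrices = out)
}

#' Identify TCR V(D)J segment genes by symbol
#'
#' Matches the HGNC-style T cell receptor segment nomenclature
#' (TRAV/TRAJ/TRAC, TRBV/TRBD/TRBJ/TRBC, and the gamma/delta loci).
#'
#' @param genes Character vector of gene symbols.
#' @return Logical vector.
#' @export
is_vdj_gene <- function(genes) {
  grepl("^TR[ABGD][VDJC]", genes)
}

#' Fit per-gene negative-binomial parameters
#'
#' Fits the depth-offset negative-binomial model underlying the
#' Pearson-residual normalization: each gene g has a mean fraction
#' \eqn{p_g} (its share of total counts) and a dispersion \eqn{\theta_g},
#' so that a cell with depth \eqn{n_c} has expectation
#' \eqn{\mu_{gc} = n_c p_g} and variance \eqn{\mu + \mu^2/\theta_g}.
#' Dispersions are estimated by method of moments on depth-scaled counts
#' (each cell rescaled to the mean depth); genes whose moment estimate is
#' non-positive (at or under Poisson dispersion) get \eqn{\theta = \infty},
#' and positive estimates are floored at 1e-4.
#'
#' @param m count matrix with at least 2 cells.
#' @return An \code{nb_params} list with \code{genes}, \code{p} (mean
#'   fractions, summing to 1) and \code{theta} (dispersions, possibly Inf).
#' @export
fit_nb_params <- function(m) {
  if (ncol(m) < 2) stop_validation("need at least 2 cells to fit")
  depths <- Matrix::colSums(m)
  grand <- sum(depths)
  if (grand == 0) stop_validation("matrix has zero total counts")
  p <- Matrix::rowSums(m) / grand
  # scale every cell to the mean depth; MoM on the scaled counts
  nbar <- mean(depths)
  sf <- ifelse(depths > 0, nbar / depths, 0)
  z <- m %*% Matrix::Diagonal(x = sf)
  mu <- Matrix::rowMeans(z)
  n <- ncol(m)
  v <- (Matrix::rowSums(z^2) - n * mu^2) / (n - 1)
  excess <- v - mu
  theta <- ifelse(excess > 0, pmax(mu^2 / excess, 1e-4), Inf)
  theta[mu == 0] <- Inf
  structure(list(genes = rownames(m), p = as.numeric(p),
                 theta = as.numeric(theta)),
            class = "nb_params")
}

#' Negative-binomial Pearson residuals
#'
#' Computes for each gene g and cell c with depth \eqn{n_c} the residual
#' \deqn{r_{gc} = (x_{gc} - \mu_{gc}) / \sqrt{\mu_{gc} + \mu_{gc}^2/\theta_g},
#'   \quad \mu_{gc} = n_c p_g,}
#' clipped to \eqn{\pm\sqrt{n_{cells}}}. The residual matrix (genes x cells,
#' dense, gene order = parameter gene order) is the classifier's feature
#' input. Genes present in \code{params} but absent from \code{m} get
#' residual 0 (the model-neutral value), which is how a trained model is
#' applied to new samples with a smaller gene set; genes in \code{m} but not
#' in \code{params} are dropped.
#'
#' @param m count matrix.
#' @param params \code{nb_params} from [fit_nb_params()].
#' @param clip Clipping bound; default \code{sqrt(ncol(m))}.
#' @return Dense residual matrix (genes x cells) with attribute
#'   \code{clip_bound}.
#' @export
pearson_residuals <- function(m, params, clip = NULL) {
  if (is.null(clip)) clip <- sqrt(ncol(m))
  depths <- Matrix::colSums(m)
  if (any(depths == 0)) warning("cell(s) with zero depth: residuals set to 0")
  genes <- params$genes
  present <- genes[genes %in% rownames(m)]
  x <- matrix(0, length(genes), ncol(m),
              dimnames = list(genes, colnames(m)))
  if (length(present))
    x[present, ] <- as.matrix(m[present, , drop = FALSE])
  p <- params$p[match(genes, params$genes)]
  theta <- params$theta[match(genes, params$genes)]
  mu <- outer(p, depths)                     # genes x cells
  denom <- sqrt(mu + mu^2 / theta)           # Inf theta -> Poisson limit
  r <- (x - mu) / denom
  r[denom == 0] <- 0                         # p_g = 0 or depth 0
  r[, depths == 0] <- 0
  missing_genes <- setdiff(genes, rownames(m))
  if (length(missing_genes)) r[missing_genes, ] <- 0
  r <- pmin(pmax(r, -clip), clip)
  attr(r, "clip_bound") <- clip
  r
}

#' Depth-normalized log expression
#'
#' \code{log1p} of counts scaled to \code{scale} total counts per cell — the
#' conventional input for additive and module-score gene signatures.
#'
#' @param m count matrix.
#' @param scale Target depth (default 10000).
#' @return Dense genes x cells matrix of log-normalized expression.
#' @export
log_normalize <- function(m, scale = 1e4) {
  depths <- Matrix::colSums(m)
  sf <- ifelse(depths > 0, scale / depths, 0)
  out <- log1p(as.matrix(m %*% Matrix::Diagonal(x = sf)))
  dimnames(out) <- dimnames(m)
  out
}
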