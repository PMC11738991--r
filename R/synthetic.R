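#' Configuration for the synthetic scRNA + VDJ generator
#'
#' The generator emulates the statistical structure of a tumor-infiltrating
#' lymphocyte (TIL) training cohort: negative-binomial UMI counts with
#' log-normal cell-depth variation; a reactive transcriptional program
#' (a small set of up-regulated genes) expressed in a subset of the cells of
#' reactive clonotypes (state mixing: cells of one clonotype occupy diverse
#' phenotypes); a power-law clonotype size distribution with reactive
#' clonotypes more expanded; and a large healthy-donor PBMC background pool
#' that dominates the training data, reproducing the strong class imbalance
#' of real training cohorts.
#'
#' @param n_genes Number of genes.
#' @param n_background_cells Healthy-donor background pool size, spread
#'   over \code{n_donors} donor pseudo-clonotypes.
#' @param n_til_cells Number of TIL cells carrying VDJ clonotypes.
#' @param n_clonotypes Number of TIL TCR clonotypes.
#' @param frac_reactive_clonotypes Fraction of clonotypes that are tumor
#'   reactive.
#' @param n_program_genes Number of reactive-program genes.
#' @param program_log2fc log2 fold-change of program genes in
#'   program-active cells.
#' @param program_cell_fraction Fraction of a reactive clonotype's cells in
#'   the program-active state.
#' @param nb_dispersion Negative-binomial dispersion theta shared by genes.
#' @param depth_meanlog,depth_sdlog Log-normal cell depth parameters.
#' @param clonotype_size_power Power-law exponent of clonotype sizes.
#' @param reactive_expansion_factor Multiplier on reactive clonotype size
#'   weights (reactive clonotypes are more expanded).
#' @param n_donors Number of healthy-donor pseudo-clonotypes.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 500,
                       n_background_cells = 3000,
                       n_til_cells = 1000,
                       n_clonotypes = 50,
                       frac_reactive_clonotypes = 0.68,
                       n_program_genes = 10,
                       program_log2fc = 2,
                       program_cell_fraction = 0.6,
                       nb_dispersion = 2,
                       depth_meanlog = log(3000),
                       depth_sdlog = 0.3,
                       clonotype_size_power = 1.5,
                       reactive_expansion_factor = 3,
                       n_donors = 10,
                       seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_program_genes > cfg$n_genes)
    stop_validation("more program genes than genes")
  stopifnot(cfg$frac_reactive_clonotypes > 0,
            cfg$frac_reactive_clonotypes <= 1,
            cfg$program_cell_fraction > 0, cfg$program_cell_fraction <= 1,
            cfg$program_log2fc >= 0, cfg$nb_dispersion > 0)
  structure(cfg, class = "sim_config")
}

#' Simulate a synthetic TIL scRNA + VDJ dataset with ground truth
#'
#' See [sim_config()] for the generative model. Counts are drawn
#' NB(mu = depth_c * p_g * fold_gc, size = theta) where fold is
#' \code{2^program_log2fc} for program genes in program-active cells of
#' reactive clonotypes and 1 otherwise; gene baseline fractions p_g are
#' log-normal; TIL clonotype sizes follow a power law with reactive
#' clonotypes' weights multiplied by the expansion factor before
#' renormalization.
#'
#' @param cfg A [sim_config()].
#' @return List with \code{counts} (sparse genes x cells matrix, TIL plus
#'   background cells), \code{clonotypes} (VDJ table covering TIL cells),
#'   \code{truth} (data.frame clonotype_id / reactive), \code{cell_info}
#'   (barcode, clonotype_id, is_til, program_active), and
#'   \code{program_genes}.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    program_genes <- sample(genes, cfg$n_program_genes)
    base <- rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1.2)
    p <- base / sum(base)
    names(p) <- genes

    n_reactive <- max(1, round(cfg$frac_reactive_clonotypes *
                                 cfg$n_clonotypes))
    clono_ids <- sprintf("clonotype%02d", seq_len(cfg$n_clonotypes))
    reactive <- c(rep(TRUE, n_reactive),
                  rep(FALSE, cfg$n_clonotypes - n_reactive))
    # power-law size weights on a random rank ordering, reactive expanded
    w <- sample(seq_len(cfg$n_clonotypes))^(-cfg$clonotype_size_power)
    w[reactive] <- w[reactive] * cfg$reactive_expansion_factor
    sizes <- pmax(1L, round(cfg$n_til_cells * w / sum(w)))

    cl_of_cell <- rep(seq_len(cfg$n_clonotypes), sizes)
    n_til <- length(cl_of_cell)
    til_bc <- sprintf("TIL-%05d", seq_len(n_til))
    active <- reactive[cl_of_cell] &
      runif(n_til) < cfg$program_cell_fraction

    donors <- rep(sprintf("HD%02d_ctrl", seq_len(cfg$n_donors)),
                  length.out = cfg$n_background_cells)
    # donor identity is recoverable from the barcode prefix
    bg_bc <- sprintf("%s-%05d", sub("_ctrl$", "", donors),
                     seq_len(cfg$n_background_cells))

    n_cells <- n_til + cfg$n_background_cells
    depths <- rlnorm(n_cells, cfg$depth_meanlog, cfg$depth_sdlog)
    fold <- 2^cfg$program_log2fc
    prog_idx <- match(program_genes, genes)

    counts <- matrix(0L, cfg$n_genes, n_cells)
    for (c in seq_len(n_cells)) {
      mu <- depths[c] * p
      if (c <= n_til && active[c]) mu[prog_idx] <- mu[prog_idx] * fold
      counts[, c] <- rnbinom(cfg$n_genes, mu = mu, size = cfg$nb_dispersion)
    }
    dimnames(counts) <- list(genes, c(til_bc, bg_bc))
    m <- new_count_matrix(counts, genes, c(til_bc, bg_bc), "synthetic")

    # VDJ rows: one TRB + one TRA per TIL cell, CDR3s shared per clonotype
    nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
    cdr3b <- vapply(seq_len(cfg$n_clonotypes), function(i) nt(36),
                    character(1))
    cdr3a <- vapply(seq_len(cfg$n_clonotypes), function(i) nt(33),
                    character(1))
    clonotypes <- data.frame(
      barcode = rep(til_bc, each = 2),
      clonotype_id = rep(clono_ids[cl_of_cell], each = 2),
      chain = rep(c("TRA", "TRB"), n_til),
      cdr3_nt = as.vector(rbind(cdr3a[cl_of_cell], cdr3b[cl_of_cell])),
      cdr3_aa = "",
      v_gene = as.vector(rbind(paste0("TRAV", cl_of_cell),
                               paste0("TRBV", cl_of_cell))),
      j_gene = as.vector(rbind(paste0("TRAJ", cl_of_cell),
                               paste0("TRBJ", cl_of_cell))),
      productive = TRUE,
      stringsAsFactors = FALSE)

    cell_info <- data.frame(
      barcode = c(til_bc, bg_bc),
      clonotype_id = c(clono_ids[cl_of_cell], donors),
      is_til = rep(c(TRUE, FALSE), c(n_til, cfg$n_background_cells)),
      program_active = c(active, rep(FALSE, cfg$n_background_cells)),
      stringsAsFactors = FALSE)

    list(counts = m,
         clonotypes = clonotypes,
         truth = data.frame(clonotype_id = clono_ids, reactive = reactive,
                            stringsAsFactors = FALSE),
         cell_info = cell_info,
         program_genes = program_genes,
         config = cfg)
  })
}

#' Simulate flow-cytometry CD107a readouts for tested TCRs
#'
#' Emulates the four-condition degranulation assay: reactive TCRs get a
#' CD107a response \code{effect} percentage points above background in the
#' "TCR vs tumor line" well; all wells carry Gaussian noise of
#' \code{noise_sd} points; mTCRbeta expression is drawn well above the 2\%
#' inclusion cut-off. With the default effect and the plate-level noise
#' (0.34), [call_tcr_reactive()] recovers the ground truth.
#'
#' @param truth data.frame with \code{clonotype_id} and \code{reactive}.
#' @param effect CD107a elevation (\%) for reactive TCRs; default 5.
#' @param noise_sd Gaussian noise s.d. (\%) on each well; default 0.34.
#' @param seed Integer seed.
#' @return data.frame of assay rows (see [read_reactivity_table()]).
#' @export
simulate_flow_readout <- function(truth, effect = 5, noise_sd = 0.34,
                                  seed = 1) {
  if (noise_sd < 0) stop_validation("noise_sd must be non-negative")
  with_seed(seed, {
    n <- nrow(truth)
    base <- 1.0
    clamp <- function(x) pmin(pmax(x, 0), 100)
    data.frame(
      tcr_id = paste0("TCR_", truth$clonotype_id),
      clonotype_id = truth$clonotype_id,
      pct_cd107a_vs_line = clamp(base + effect * truth$reactive +
                                   rnorm(n, 0, noise_sd)),
      pct_cd107a_unstim = clamp(base + rnorm(n, 0, noise_sd)),
      pct_cd107a_mock_vs_line = clamp(base + rnorm(n, 0, noise_sd)),
      pct_cd107a_mock_unstim = clamp(base + rnorm(n, 0, noise_sd)),
      pct_mtcrb = round(runif(n, 20, 80), 1),
      stringsAsFactors = FALSE)
  })
}
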