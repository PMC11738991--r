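# Shared fixtures and independent oracles, all built in code at test time.

# half-up rounding to 2 decimals, written out so display-rounding checks
# do not depend on the package's own helper
round_half_up_test <- function(x) floor(x * 100 + 0.5) / 100

# small deterministic count matrix
toy_counts <- function(mat, genes = NULL, barcodes = NULL) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(mat)))
  if (is.null(barcodes)) barcodes <- sprintf("cell%02d", seq_len(ncol(mat)))
  count_matrix(mat, genes, barcodes, sample_id = "toy")
}

# write a 10x-style MTX triplet for a matrix; returns the directory
write_triplet <- function(m, dir = tempfile("mtx")) {
  dir.create(dir)
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                              "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  write.table(data.frame(rownames(m), rownames(m), "Gene Expression"),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  dir
}

# small contig annotation data.frame in the Cell Ranger dialect
toy_contigs <- function() {
  data.frame(
    barcode = c("bc1", "bc1", "bc2", "bc2"),
    chain = c("TRA", "TRB", "TRA", "TRB"),
    cdr3 = c("CAV1", "CASS1", "CAV2", "CASS2"),
    cdr3_nt = c("TGTGCA", "TGTGCC", "TGTGCG", "TGTGCT"),
    v_gene = c("TRAV1", "TRBV1", "TRAV2", "TRBV2"),
    j_gene = c("TRAJ1", "TRBJ1", "TRAJ2", "TRBJ2"),
    productive = c("true", "true", "true", "true"),
    raw_clonotype_id = c("c1", "c1", "c2", "c2"),
    stringsAsFactors = FALSE)
}

# exhaustive 2-class Fisher-Jenks: minimize within-class SSD over all
# contiguous splits of the sorted values; returns min of upper class
brute_jenks2 <- function(values) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  best <- Inf; thr <- NA
  for (i in 1:(n - 1)) {
    s <- ssd(x[1:i]) + ssd(x[(i + 1):n])
    if (s < best) { best <- s; thr <- x[i + 1] }
  }
  thr
}

# brute-force AUC: fraction of (positive, negative) pairs won, ties half
brute_auc <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exact interventional Shapley values by subset enumeration (<= ~5 features)
# for a prediction function f(matrix)->margin, background rows X
exact_shapley <- function(f, x, X) {
  d <- length(x)
  subsets <- lapply(0:(2^d - 1),
                    function(m) which(bitwAnd(m, 2^(0:(d - 1))) > 0))
  key <- function(S) paste0("s", paste(S, collapse = ","))
  v <- new.env()
  for (S in subsets) {
    M <- X
    if (length(S)) M[, S] <- matrix(rep(x[S], each = nrow(X)), nrow(X))
    assign(key(S), mean(f(M)), v)
  }
  phi <- numeric(d)
  for (i in seq_len(d)) for (S in subsets) {
    if (i %in% S) next
    s <- length(S)
    w <- factorial(s) * factorial(d - s - 1) / factorial(d)
    phi[i] <- phi[i] + w * (get(key(sort(c(S, i))), v) - get(key(S), v))
  }
  phi
}

# tiny but non-degenerate simulated dataset for pipeline-level tests
tiny_sim <- function(seed = 3, log2fc = 3, cell_fraction = 0.6) {
  simulate_dataset(sim_config(
    n_genes = 80, n_background_cells = 300, n_til_cells = 240,
    n_clonotypes = 12, n_program_genes = 5, program_log2fc = log2fc,
    program_cell_fraction = cell_fraction, n_donors = 4, seed = seed))
}

# thin a training set to every n-th cell (keeps both classes)
subset_training_set_test <- function(ts, keep) {
  training_set(ts$residuals[, keep, drop = FALSE], ts$barcode[keep],
               ts$label[keep], ts$clonotype_id[keep], ts$provenance[keep])
}

# training set from simulator output (mirrors the pipeline wiring)
sim_training_set <- function(sim, residuals = NULL) {
  if (is.null(residuals)) {
    prm <- fit_nb_params(sim$counts)
    residuals <- pearson_residuals(sim$counts, prm)
  }
  info <- sim$cell_info
  lab <- ifelse(info$is_til,
                sim$truth$reactive[match(info$clonotype_id,
                                         sim$truth$clonotype_id)],
                FALSE)
  training_set(residuals, info$barcode, lab, info$clonotype_id,
               ifelse(info$is_til, "TIL", "control"))
}
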