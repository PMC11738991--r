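# File-oriented pipeline commands. Each is a thin orchestration over the
# package API so a shell entry point (inst/cli/reactcr.R) and tests share
# one code path. All commands are deterministic given their seed.

write_mtx_triplet <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  write.table(data.frame(id = rownames(m), symbol = rownames(m),
                         type = "Gene Expression"),
              file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Simulate a dataset to disk
#'
#' Writes the MTX triplet, the VDJ contig table, the simulated flow
#' readouts and a truth manifest into \code{out_dir}.
#'
#' @param out_dir Output directory.
#' @param cfg A [sim_config()].
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(out_dir, cfg = sim_config()) {
  sim <- simulate_dataset(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_mtx_triplet(sim$counts, file.path(out_dir, "counts"))
  contigs <- data.frame(barcode = sim$clonotypes$barcode,
                        chain = sim$clonotypes$chain,
                        cdr3 = sim$clonotypes$cdr3_aa,
                        cdr3_nt = sim$clonotypes$cdr3_nt,
                        v_gene = sim$clonotypes$v_gene,
                        j_gene = sim$clonotypes$j_gene,
                        productive = sim$clonotypes$productive,
                        raw_clonotype_id = sim$clonotypes$clonotype_id,
                        stringsAsFactors = FALSE)
  write.csv(contigs, file.path(out_dir, "contig_annotations.csv"),
            row.names = FALSE, quote = FALSE)
  flow <- simulate_flow_readout(sim$truth, seed = cfg$seed)
  write.csv(flow, file.path(out_dir, "reactivity.csv"),
            row.names = FALSE, quote = FALSE)
  manifest <- list(seed = cfg$seed, config = unclass(cfg),
                   truth = sim$truth, program_genes = sim$program_genes,
                   cell_info = sim$cell_info)
  jsonlite::write_json(manifest, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(counts = file.path(out_dir, "counts"),
                 contigs = file.path(out_dir, "contig_annotations.csv"),
                 reactivity = file.path(out_dir, "reactivity.csv"),
                 truth = file.path(out_dir, "truth.json")))
}

# labeled training set from simulator output (controls = background donors)
training_set_from_sim <- function(sim, residuals = NULL) {
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

#' Train the classifier from files on disk
#'
#' Reads the counts, contig annotations and flow reactivity table written
#' by [run_simulate()] (or equivalent real inputs), derives binary labels
#' with the 2 s.d. CD107a rule, QC-filters and normalizes the counts,
#' trains the two-stage model and writes both stages plus a JSON training
#' report to \code{out_dir}.
#'
#' @param data_dir Directory holding \code{counts/},
#'   \code{contig_annotations.csv}, \code{reactivity.csv}.
#' @param out_dir Output directory for models and report.
#' @param k,budget,n_top,train_fraction,seed Training controls (see
#'   [reactcr()]).
#' @param sd_unstim Unstimulated CD107a s.d. for the labeling rule.
#' @param min_total,min_features QC thresholds (see [filter_cells()]).
#' @return The fitted \code{reactcr} object, invisibly.
#' @export
run_train <- function(data_dir, out_dir, k = 10, budget = 30, n_top = 100,
                      train_fraction = 0.7, seed = 1, sd_unstim = 0.34,
                      min_total = 1200, min_features = 500) {
  counts <- read_count_matrix(file.path(data_dir, "counts"))
  contigs <- read_contig_annotations(
    file.path(data_dir, "contig_annotations.csv"))
  assays <- read_reactivity_table(file.path(data_dir, "reactivity.csv"))
  counts <- filter_cells(counts, min_total, min_features)
  assays <- call_tcr_reactive(assays, sd_unstim = sd_unstim)
  contigs <- contigs[contigs$barcode %in% colnames(counts), , drop = FALSE]
  control_bc <- setdiff(colnames(counts), contigs$barcode)
  labels <- propagate_labels(assays, contigs, control_barcodes = control_bc)
  # controls grouped into donor pseudo-clonotypes by barcode prefix
  ctrl <- is.na(labels$clonotype_id)
  labels$clonotype_id[ctrl] <-
    paste0("ctrl_", sub("-.*$", "", labels$barcode[ctrl]))
  prm <- fit_nb_params(counts)
  res <- pearson_residuals(counts, prm)
  ts <- training_set(res, labels$barcode, labels$label,
                     labels$clonotype_id,
                     ifelse(ctrl, "control", "TIL"))
  fit <- reactcr(ts, train_fraction = train_fraction, k = k,
                 budget = budget, n_top = n_top, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_model(fit$intermediate, file.path(out_dir, "model_intermediate"))
  write_model(fit$final, file.path(out_dir, "model_final"))
  saveRDS(prm, file.path(out_dir, "nb_params.rds"))
  report <- list(seed = seed, k = k, budget = budget, n_top = n_top,
                 cv_auc = as.list(fit$cv_auc),
                 test_auc = fit$test_auc,
                 n_final_features = length(fit$final$features),
                 final_features = fit$final$features)
  jsonlite::write_json(report, file.path(out_dir, "training_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Predict clonotype reactivity for a sample on disk
#'
#' @param model_dir Directory from [run_train()] (uses the final model and
#'   its NB normalization parameters).
#' @param data_dir Directory with \code{counts/} and
#'   \code{contig_annotations.csv} for the sample to score.
#' @param out_dir Output directory (\code{clonotype_scores.csv},
#'   \code{call_report.json}).
#' @param min_cells Minimum cells per scored clonotype.
#' @param q Optional percentile (0-1); when set, an additional
#'   \code{prioritized.csv} keeps only clonotypes above that score
#'   percentile.
#' @return The clonotype score data.frame, invisibly.
#' @export
run_predict <- function(model_dir, data_dir, out_dir, min_cells = 1,
                        q = NULL) {
  model <- read_model(file.path(model_dir, "model_final"))
  prm <- readRDS(file.path(model_dir, "nb_params.rds"))
  counts <- read_count_matrix(file.path(data_dir, "counts"))
  contigs <- read_contig_annotations(
    file.path(data_dir, "contig_annotations.csv"))
  res <- pearson_residuals(counts, prm)
  probs <- predict_cell_probabilities(model, res)
  scores <- call_reactive(
    score_clonotypes(probs, contigs, min_cells = min_cells))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_clonotype_scores(scores, file.path(out_dir, "clonotype_scores.csv"))
  jsonlite::write_json(
    list(threshold = scores$threshold[1],
         n_reactive = sum(scores$call == "reactive"),
         n_clonotypes = nrow(scores)),
    file.path(out_dir, "call_report.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(q))
    write.csv(percentile_filter(scores, q),
              file.path(out_dir, "prioritized.csv"), row.names = FALSE)
  invisible(scores)
}

#' Run a signature baseline over a sample on disk
#'
#' @param data_dir Directory with \code{counts/} and
#'   \code{contig_annotations.csv}.
#' @param signature_file Gene list file (see [read_signature()]).
#' @param method Scoring method (\code{ssgsea}, \code{additive},
#'   \code{module}, \code{rank_u}).
#' @param out_dir Output directory.
#' @param seed Seed for the module-score control draw.
#' @return Clonotype score data.frame, invisibly.
#' @export
run_signatures <- function(data_dir, signature_file, method, out_dir,
                           seed = 1) {
  sig <- read_signature(signature_file, method = method)
  counts <- read_count_matrix(file.path(data_dir, "counts"))
  contigs <- read_contig_annotations(
    file.path(data_dir, "contig_annotations.csv"))
  scores <- score_signature(counts, sig, seed = seed)
  calls <- signature_clonotype_calls(scores, contigs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(scores, file.path(out_dir, "cell_scores.csv"),
            row.names = FALSE)
  write_clonotype_scores(calls, file.path(out_dir, "clonotype_scores.csv"))
  invisible(calls)
}

#' Evaluate clonotype calls against experimental truth
#'
#' @param scores_file \code{clonotype_scores.csv} from [run_predict()] or
#'   [run_signatures()].
#' @param truth_file CSV with columns \code{clonotype_id} and
#'   \code{reactive} (logical or \code{reactive}/\code{nonreactive}).
#' @param out_file JSON report path.
#' @return Metrics list, invisibly.
#' @export
run_evaluate <- function(scores_file, truth_file, out_file) {
  scores <- read.csv(scores_file, stringsAsFactors = FALSE)
  truth <- read.csv(truth_file, stringsAsFactors = FALSE)
  common <- intersect(scores$clonotype_id, truth$clonotype_id)
  if (!length(common))
    stop_validation("no clonotypes shared between scores and truth")
  scores <- scores[match(common, scores$clonotype_id), ]
  tv <- truth$reactive[match(common, truth$clonotype_id)]
  if (is.character(tv)) tv <- tv == "reactive" | tv == "TRUE"
  calls <- setNames(scores$call, common)
  names(tv) <- common
  res <- evaluate_calls(calls, tv,
                        setNames(scores$mean_probability, common))
  out <- list(tp = res$confusion$tp, fp = res$confusion$fp,
              tn = res$confusion$tn, fn = res$confusion$fn,
              accuracy = res$accuracy, g_mean = res$g_mean, auc = res$auc)
  jsonlite::write_json(out, out_file, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(res)
}
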