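#' Fit the two-stage tumor-reactivity classifier
#'
#' End-to-end training of the reactivity classifier on labeled cells:
#' \enumerate{
#'   \item split clonotypes (not cells) 70/30 into train and test,
#'     stratified by label, so no clonotype leaks across the split;
#'   \item tune XGBoost hyperparameters by sequential model-based
#'     optimization of stratified k-fold cell-level CV AUC and fit the
#'     intermediate full-feature model;
#'   \item rank genes by mean absolute Shapley value on the training cells;
#'   \item re-tune and refit on the top \code{n_top} genes (final model);
#'   \item score the held-out clonotypes: per-cell probabilities are
#'     averaged per clonotype, the sample-specific Fisher-Jenks threshold
#'     is computed on those means, and clonotype-level AUC is reported.
#' }
#'
#' @param ts A [training_set()] of labeled cells (TILs with tested
#'   clonotypes plus healthy-donor controls under donor pseudo-clonotypes).
#' @param train_fraction Fraction of clonotypes per class used for
#'   training.
#' @param k CV folds for hyperparameter tuning.
#' @param budget Hyperparameter evaluations per tuning stage (>= 10).
#' @param n_top Number of Shapley-selected genes in the final model.
#' @param seed Integer seed governing split, tuning and fits.
#' @return An object of class \code{reactcr}; see
#'   \code{print}/\code{summary}/\code{predict}/\code{coef}/\code{plot}
#'   methods.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(sim_config(n_genes = 60, n_background_cells = 150,
#'                                    n_til_cells = 150, n_clonotypes = 12,
#'                                    seed = 1))
#' prm <- fit_nb_params(sim$counts)
#' res <- pearson_residuals(sim$counts, prm)
#' info <- sim$cell_info
#' lab <- ifelse(info$is_til,
#'               sim$truth$reactive[match(info$clonotype_id,
#'                                        sim$truth$clonotype_id)],
#'               FALSE)
#' ts <- training_set(res, info$barcode, lab, info$clonotype_id,
#'                    ifelse(info$is_til, "TIL", "control"))
#' fit <- reactcr(ts, k = 3, budget = 10, n_top = 20, seed = 1)
#' print(fit)
#' }
#' @export
reactcr <- function(ts, train_fraction = 0.7, k = 10, budget = 30,
                    n_top = 100, seed = 1) {
  stopifnot(inherits(ts, "training_set"))
  sp <- split_by_clonotype(ts, train_fraction, seed = seed)
  stopifnot(length(intersect(unique(sp$train$clonotype_id),
                             unique(sp$test$clonotype_id))) == 0)
  hp1 <- tune_hyperparameters(sp$train, k = k, budget = budget, seed = seed)
  intermediate <- fit_model(sp$train, hp1, seed = seed,
                            stage = "intermediate")
  ranking <- shap_feature_ranking(intermediate, sp$train$residuals)
  n_top <- min(n_top, nrow(ranking))
  final <- retrain_top_features(sp$train, ranking, n_top = n_top, k = k,
                                budget = budget, seed = seed)

  # held-out evaluation at the clonotype level
  test_probs <- predict_cell_probabilities(final, sp$test$residuals)
  cl <- data.frame(barcode = sp$test$barcode,
                   clonotype_id = sp$test$clonotype_id,
                   stringsAsFactors = FALSE)
  scores <- score_clonotypes(test_probs, cl)
  truth <- tapply(sp$test$label, sp$test$clonotype_id, function(l) l[1])
  truth <- truth[scores$clonotype_id]
  test_auc <- roc_auc(scores$mean_probability, as.logical(truth))
  calls <- tryCatch(call_reactive(scores), error = function(e) NULL)

  structure(list(intermediate = intermediate, final = final,
                 ranking = ranking,
                 cv_auc = c(intermediate = attr(hp1, "cv_auc"),
                            final = attr(final$hyperparams, "cv_auc")),
                 test_scores = scores,
                 test_truth = as.logical(truth),
                 test_auc = test_auc,
                 test_calls = calls,
                 n_train_cells = length(sp$train$barcode),
                 n_test_cells = length(sp$test$barcode),
                 train_clonotypes = sort(unique(sp$train$clonotype_id)),
                 test_clonotypes = sort(unique(sp$test$clonotype_id)),
                 seed = seed,
                 call = match.call()),
            class = "reactcr")
}

#' @export
print.reactcr <- function(x, ...) {
  cat("Two-stage boosted-tree tumor-reactivity classifier\n")
  cat(sprintf("  training cells: %d   held-out cells: %d\n",
              x$n_train_cells, x$n_test_cells))
  cat(sprintf("  final model features: %d (Shapley-selected)\n",
              length(x$final$features)))
  cat(sprintf("  CV AUC (cell level): intermediate %.3f, final %.3f\n",
              x$cv_auc["intermediate"], x$cv_auc["final"]))
  cat(sprintf("  held-out clonotype-level AUC: %.3f (%d clonotypes)\n",
              x$test_auc, nrow(x$test_scores)))
  if (!is.null(x$test_calls))
    cat(sprintf("  Fisher-Jenks threshold on held-out scores: %.3f\n",
                x$test_calls$threshold[1]))
  invisible(x)
}

#' @export
summary.reactcr <- function(object, ...) {
  print(object)
  cat("\nTop 10 genes by mean |Shapley value|:\n")
  print(head(object$ranking, 10), row.names = FALSE)
  if (!is.null(object$test_calls)) {
    cc <- confusion(
      setNames(object$test_calls$call, object$test_calls$clonotype_id),
      setNames(object$test_truth, object$test_calls$clonotype_id))
    cat("\nHeld-out clonotype calls vs experimental truth:\n")
    print(cc)
    cat(sprintf("  accuracy %.2f  G-mean %.2f\n",
                accuracy(cc), g_mean(cc)))
  }
  invisible(object)
}

#' Predict reactivity for a new sample
#'
#' @param object A fitted \code{reactcr} object.
#' @param residuals Residual matrix for the new sample (genes x cells);
#'   model genes absent from the sample are imputed at residual 0.
#' @param clonotypes Optional clonotype table; when given, per-clonotype
#'   mean scores and Fisher-Jenks calls are returned, otherwise per-cell
#'   probabilities.
#' @param min_cells Minimum cells per scored clonotype.
#' @param ... Unused.
#' @return Named per-cell probability vector, or a clonotype score
#'   data.frame with threshold and calls.
#' @export
predict.reactcr <- function(object, residuals, clonotypes = NULL,
                            min_cells = 1, ...) {
  probs <- predict_cell_probabilities(object$final, residuals)
  if (is.null(clonotypes)) return(probs)
  scores <- score_clonotypes(probs, clonotypes, min_cells = min_cells)
  call_reactive(scores)
}

#' @export
coef.reactcr <- function(object, ...) {
  setNames(object$ranking$importance, object$ranking$gene)
}

#' @export
plot.reactcr <- function(x, n_top = 20, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 6, 2, 1))
  on.exit(par(op))
  top <- head(x$ranking, n_top)
  barplot(rev(top$importance), names.arg = rev(top$gene), horiz = TRUE,
          las = 1, cex.names = 0.6, xlab = "mean |Shapley value|",
          main = "Feature importance")
  hist(x$test_scores$mean_probability, breaks = 20,
       xlab = "clonotype mean probability", main = "Held-out scores")
  if (!is.null(x$test_calls))
    abline(v = x$test_calls$threshold[1], col = "red", lty = 2)
  invisible(x)
}

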