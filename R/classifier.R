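#' Assemble a training set for the reactivity classifier
#'
#' @param residuals Pearson-residual matrix (genes x cells) from
#'   [pearson_residuals()].
#' @param barcode Character vector of labeled cell barcodes (must be
#'   columns of \code{residuals}).
#' @param label Binary labels per barcode (\code{"reactive"} /
#'   \code{"nonreactive"}, or logical).
#' @param clonotype_id Clonotype of each labeled cell; healthy-donor
#'   control cells should carry a per-donor pseudo-clonotype so the
#'   clonotype-wise split can group them.
#' @param provenance Optional \code{"TIL"} / \code{"control"} tag per cell.
#' @return A \code{training_set} list.
#' @export
training_set <- function(residuals, barcode, label, clonotype_id,
                         provenance = NULL) {
  if (is.character(label)) label <- label == "reactive"
  label <- as.logical(label)
  miss <- setdiff(barcode, colnames(residuals))
  if (length(miss))
    stop_validation(length(miss), " labeled cell(s) lack residual columns")
  if (length(unique(label)) < 2)
    stop_validation("training set must contain both classes")
  structure(list(residuals = residuals[, barcode, drop = FALSE],
                 barcode = barcode, label = label,
                 clonotype_id = clonotype_id,
                 provenance = if (is.null(provenance))
                   rep("TIL", length(barcode)) else provenance),
            class = "training_set")
}

subset_training_set <- function(ts, keep) {
  structure(list(residuals = ts$residuals[, keep, drop = FALSE],
                 barcode = ts$barcode[keep], label = ts$label[keep],
                 clonotype_id = ts$clonotype_id[keep],
                 provenance = ts$provenance[keep]),
            class = "training_set")
}

#' Split a training set by clonotype
#'
#' Clonotypes — not cells — are partitioned into train and test so that no
#' clonotype leaks across the split; the partition is stratified by the
#' clonotype's label. All cells of a clonotype land on one side.
#'
#' @param ts A [training_set()].
#' @param train_fraction Fraction of clonotypes per class assigned to
#'   training (default 0.7).
#' @param seed Integer seed; the split is deterministic given it.
#' @return List with \code{train} and \code{test} training sets.
#' @export
split_by_clonotype <- function(ts, train_fraction = 0.7, seed = 1) {
  cl_label <- tapply(ts$label, ts$clonotype_id, function(l) l[1])
  for (cls in c(TRUE, FALSE)) {
    if (sum(cl_label == cls) < 2)
      stop_validation("need at least 2 clonotypes per class to split")
  }
  with_seed(seed, {
    train_ids <- character()
    for (cls in c(TRUE, FALSE)) {
      ids <- sort(names(cl_label)[cl_label == cls])
      n_train <- max(1, min(length(ids) - 1,
                            round(train_fraction * length(ids))))
      train_ids <- c(train_ids, sample(ids, n_train))
    }
    keep <- ts$clonotype_id %in% train_ids
    list(train = subset_training_set(ts, keep),
         test = subset_training_set(ts, !keep))
  })
}

# --- hyperparameter search space -------------------------------------------

# Search box per tunable XGBoost parameter. scale_pos_weight is anchored at
# the training class ratio (neg/pos) since weighting is the main lever on
# heavily imbalanced pools.
hp_space <- function(imbalance_ratio, tune_scale_pos_weight = TRUE) {
  sp <- list(
    learning_rate    = list(lo = 0.01, hi = 0.3, log = TRUE,  int = FALSE),
    max_depth        = list(lo = 2,    hi = 10,  log = FALSE, int = TRUE),
    n_estimators     = list(lo = 50,   hi = 600, log = FALSE, int = TRUE),
    subsample        = list(lo = 0.5,  hi = 1,   log = FALSE, int = FALSE),
    colsample_bytree = list(lo = 0.5,  hi = 1,   log = FALSE, int = FALSE),
    gamma            = list(lo = 0,    hi = 5,   log = FALSE, int = FALSE),
    min_child_weight = list(lo = 1,    hi = 20,  log = FALSE, int = FALSE),
    max_delta_step   = list(lo = 0,    hi = 10,  log = FALSE, int = FALSE),
    alpha            = list(lo = 1e-3, hi = 10,  log = TRUE,  int = FALSE),
    lambda           = list(lo = 1e-3, hi = 10,  log = TRUE,  int = FALSE))
  if (tune_scale_pos_weight)
    sp$scale_pos_weight <- list(lo = 0.1 * imbalance_ratio,
                                hi = 10 * imbalance_ratio,
                                log = TRUE, int = FALSE)
  sp
}

# map unit-cube rows to parameter lists
decode_hp <- function(u, space) {
  hp <- list()
  for (j in seq_along(space)) {
    s <- space[[j]]
    v <- if (s$log) exp(log(s$lo) + u[j] * (log(s$hi) - log(s$lo)))
         else s$lo + u[j] * (s$hi - s$lo)
    if (s$int) v <- as.integer(round(v))
    hp[[names(space)[j]]] <- v
  }
  class(hp) <- "hyper_params"
  hp
}

hp_to_xgb_params <- function(hp) {
  list(objective = "binary:logistic",
       eval_metric = "auc",
       tree_method = "hist",
       max_bin = 64,
       nthread = 1,
       eta = hp$learning_rate,
       max_depth = hp$max_depth,
       subsample = hp$subsample,
       colsample_bytree = hp$colsample_bytree,
       gamma = hp$gamma,
       min_child_weight = hp$min_child_weight,
       max_delta_step = hp$max_delta_step,
       alpha = hp$alpha,
       lambda = hp$lambda,
       scale_pos_weight = if (is.null(hp$scale_pos_weight)) 1
                          else hp$scale_pos_weight)
}

# stratified k-fold assignment on binary labels
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

# mean stratified k-fold cell-level CV AUC for one hyperparameter point
cv_auc <- function(X, y, hp, k, fold) {
  aucs <- numeric(k)
  params <- hp_to_xgb_params(hp)
  for (f in seq_len(k)) {
    tr <- fold != f
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE],
                                label = as.numeric(y[tr]))
    bst <- xgboost::xgb.train(params = params, data = dtr,
                              nrounds = hp$n_estimators, verbose = 0)
    p <- predict(bst, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
    aucs[f] <- roc_auc(p, y[!tr])
  }
  mean(aucs)
}

#' Tune XGBoost hyperparameters by sequential model-based optimization
#'
#' Maximizes mean stratified k-fold cell-level cross-validation AUC over the
#' declared search box with a Bayesian-style sequential optimizer: a Latin
#' hypercube initial design followed by iterations that fit a random-forest
#' surrogate to the observed (hyperparameters, AUC) pairs and evaluate the
#' candidate maximizing an upper-confidence-bound acquisition over a random
#' candidate pool. Deterministic given \code{seed}.
#'
#' @param train A [training_set()].
#' @param k Number of CV folds (default 10). Folds are stratified on cell
#'   labels; a degenerate single-class fold is redrawn once.
#' @param budget Total number of hyperparameter evaluations (>= 10).
#' @param seed Integer seed.
#' @param tune_scale_pos_weight Set \code{FALSE} to drop class weighting
#'   from the search (fixed at 1) — used to probe the value of weighting on
#'   imbalanced data.
#' @return \code{hyper_params} list with attributes \code{cv_auc} (best
#'   mean CV AUC) and \code{history} (all evaluated points).
#' @export
tune_hyperparameters <- function(train, k = 10, budget = 30, seed = 1,
                                 tune_scale_pos_weight = TRUE) {
  if (budget < 10) stop_validation("optimization budget must be >= 10")
  X <- t(train$residuals)
  y <- train$label
  ratio <- sum(!y) / sum(y)
  space <- hp_space(ratio, tune_scale_pos_weight)
  d <- length(space)
  with_seed(seed, {
    fold <- stratified_folds(y, k)
    bad <- vapply(seq_len(k), function(f)
      length(unique(y[fold == f])) < 2, logical(1))
    if (any(bad)) {
      fold <- stratified_folds(y, k)
      bad <- vapply(seq_len(k), function(f)
        length(unique(y[fold == f])) < 2, logical(1))
      if (any(bad)) stop_validation("degenerate single-class CV fold")
    }
    n0 <- max(8, ceiling(budget / 2))
    n0 <- min(n0, budget)
    U <- lhs::maximinLHS(n0, d)
    evals <- list()
    for (i in seq_len(n0)) {
      hp <- decode_hp(U[i, ], space)
      evals[[i]] <- list(u = U[i, ], hp = hp, auc = cv_auc(X, y, hp, k, fold))
    }
    while (length(evals) < budget) {
      obs <- do.call(rbind, lapply(evals, `[[`, "u"))
      auc_obs <- vapply(evals, `[[`, numeric(1), "auc")
      df <- as.data.frame(obs); df$y <- auc_obs
      rf <- ranger::ranger(y ~ ., data = df, num.trees = 200,
                           min.node.size = 2, seed = length(evals))
      cand <- matrix(runif(500 * d), ncol = d)
      cdf <- as.data.frame(cand); names(cdf) <- names(df)[seq_len(d)]
      pr <- predict(rf, data = cdf, predict.all = TRUE)$predictions
      mu <- rowMeans(pr); sdev <- apply(pr, 1, sd)
      pick <- which.max(mu + sdev)
      hp <- decode_hp(cand[pick, ], space)
      evals[[length(evals) + 1]] <-
        list(u = cand[pick, ], hp = hp, auc = cv_auc(X, y, hp, k, fold))
    }
    aucs <- vapply(evals, `[[`, numeric(1), "auc")
    best <- evals[[which.max(aucs)]]$hp
    attr(best, "cv_auc") <- max(aucs)
    attr(best, "history") <- data.frame(
      eval = seq_along(aucs), cv_auc = aucs)
    best
  })
}

#' Fit a gradient-boosted reactivity model
#'
#' Regularized gradient-boosted decision trees (XGBoost) on cell-level
#' Pearson residuals, with positive-class weighting via
#' \code{scale_pos_weight}. Reproducible given \code{seed} (single-threaded
#' histogram tree construction).
#'
#' @param train A [training_set()].
#' @param hp \code{hyper_params} from [tune_hyperparameters()].
#' @param seed Integer seed.
#' @param stage \code{"intermediate"} (full feature space) or
#'   \code{"final"} (post feature selection).
#' @return A \code{reactcr_model}: booster, ordered feature list,
#'   hyperparameters, seed, stage.
#' @export
fit_model <- function(train, hp, seed = 1, stage = "intermediate") {
  if (length(unique(train$label)) < 2)
    stop_validation("single-class training input")
  X <- t(train$residuals)
  y <- as.numeric(train$label)
  with_seed(seed, {
    dtr <- xgboost::xgb.DMatrix(X, label = y)
    bst <- xgboost::xgb.train(params = hp_to_xgb_params(hp), data = dtr,
                              nrounds = hp$n_estimators, verbose = 0)
    structure(list(booster = bst, features = colnames(X), hyperparams = hp,
                   seed = seed, stage = stage),
              class = "reactcr_model")
  })
}

# cells x features design matrix aligned to a model's feature list;
# missing genes are imputed at residual 0 (the model-neutral value)
align_features <- function(model, residuals) {
  present <- intersect(model$features, rownames(residuals))
  if (!length(present))
    stop_validation("no overlap between model features and residual genes")
  X <- matrix(0, ncol(residuals), length(model$features),
              dimnames = list(colnames(residuals), model$features))
  X[, present] <- t(as.matrix(residuals[present, , drop = FALSE]))
  X
}

#' Per-cell reactivity probabilities
#'
#' @param model A \code{reactcr_model}.
#' @param residuals Residual matrix (genes x cells); genes missing from the
#'   model's feature list are dropped, model features missing from the
#'   matrix are imputed at 0.
#' @return Named numeric vector of probabilities in [0, 1], one per cell.
#' @export
predict_cell_probabilities <- function(model, residuals) {
  X <- align_features(model, residuals)
  p <- predict(model$booster, xgboost::xgb.DMatrix(X))
  names(p) <- rownames(X)
  p
}

#' Rank genes by mean absolute Shapley value
#'
#' Computes exact TreeSHAP attributions of the boosted ensemble for every
#' cell in \code{residuals} and ranks genes by the mean absolute Shapley
#' value; ties are broken by feature-list order.
#'
#' @param model A \code{reactcr_model}.
#' @param residuals Residual matrix over the model's feature space.
#' @return data.frame \code{gene}, \code{importance}, \code{rank}, ordered
#'   by rank.
#' @export
shap_feature_ranking <- function(model, residuals) {
  if (!all(model$features %in% rownames(residuals)))
    stop_validation("residual matrix does not cover the model feature space")
  X <- align_features(model, residuals)
  contrib <- predict(model$booster, xgboost::xgb.DMatrix(X),
                     predcontrib = TRUE)
  contrib <- contrib[, colnames(contrib) != "(Intercept)" &
                       colnames(contrib) != "BIAS", drop = FALSE]
  imp <- colMeans(abs(contrib))
  ord <- order(-imp, seq_along(imp))   # ties: feature-list order
  data.frame(gene = model$features[ord], importance = unname(imp[ord]),
             rank = seq_along(imp), stringsAsFactors = FALSE)
}

#' Retrain on the top-ranked features
#'
#' Restricts the feature space to the \code{n_top} highest-ranked genes,
#' re-tunes hyperparameters on that space and fits the final-stage model —
#' the simplification step that protects against overfitting to the
#' training sample.
#'
#' @param train A [training_set()].
#' @param ranking Feature ranking from [shap_feature_ranking()].
#' @param n_top Number of genes to keep (default 100; >= 2).
#' @param k,budget,seed Passed to [tune_hyperparameters()] /
#'   [fit_model()].
#' @return Final-stage \code{reactcr_model}.
#' @export
retrain_top_features <- function(train, ranking, n_top = 100, k = 10,
                                 budget = 30, seed = 1) {
  if (n_top < 2) stop_validation("n_top must be >= 2")
  if (n_top > nrow(ranking))
    stop_validation("n_top exceeds the number of ranked features")
  top <- ranking$gene[seq_len(n_top)]
  sub <- train
  sub$residuals <- train$residuals[top, , drop = FALSE]
  hp <- tune_hyperparameters(sub, k = k, budget = budget, seed = seed)
  fit_model(sub, hp, seed = seed, stage = "final")
}

#' Save / load a trained reactivity model
#'
#' The booster is serialized to XGBoost's JSON format next to a metadata
#' JSON (feature list, hyperparameters, seed, stage, format version).
#'
#' @param model A \code{reactcr_model}.
#' @param dir Directory to write \code{booster.json} and
#'   \code{metadata.json} into.
#' @return \code{dir}, invisibly.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(model$booster, file.path(dir, "booster.json"))
  meta <- list(format_version = 1L, features = model$features,
               hyperparams = unclass(model$hyperparams),
               seed = model$seed, stage = model$stage)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  bf <- file.path(dir, "booster.json")
  mf <- file.path(dir, "metadata.json")
  if (!file.exists(bf) || !file.exists(mf))
    stop_format("model directory must contain booster.json and metadata.json")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  hp <- meta$hyperparams; class(hp) <- "hyper_params"
  structure(list(booster = xgboost::xgb.load(bf),
                 features = meta$features, hyperparams = hp,
                 seed = meta$seed, stage = meta$stage),
            class = "reactcr_model")
}
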