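# small labeled training set with a clean 2-gene signal
toy_training_set <- function(n_clono = 10, cells_per = 6, effect = 5,
                             seed = 1) {
  set.seed(seed)
  n <- n_clono * cells_per
  lab_clono <- rep(c(TRUE, FALSE), length.out = n_clono)
  clono <- rep(sprintf("c%02d", seq_len(n_clono)), each = cells_per)
  y <- lab_clono[rep(seq_len(n_clono), each = cells_per)]
  res <- matrix(rnorm(4 * n), 4, n,
                dimnames = list(paste0("G", 1:4), paste0("b", seq_len(n))))
  res[1, y] <- res[1, y] + effect
  training_set(res, colnames(res), y, clono)
}

test_that("clonotype split is stratified, exact and deterministic", {
  ts <- toy_training_set(n_clono = 20)
  sp <- split_by_clonotype(ts, 0.7, seed = 4)
  train_cl <- unique(sp$train$clonotype_id)
  test_cl <- unique(sp$test$clonotype_id)
  expect_length(train_cl, 14)   # 7 + 7 of 10 + 10
  expect_length(test_cl, 6)
  lab <- tapply(ts$label, ts$clonotype_id, `[`, 1)
  expect_equal(sum(lab[train_cl]), 7)

  sp2 <- split_by_clonotype(ts, 0.7, seed = 4)
  expect_identical(sp$train$barcode, sp2$train$barcode)
})

test_that("no clonotype ever straddles the split", {
  ts <- toy_training_set(n_clono = 9, cells_per = 4)
  for (seed in 1:100) {
    sp <- split_by_clonotype(ts, 0.7, seed = seed)
    expect_length(intersect(unique(sp$train$clonotype_id),
                            unique(sp$test$clonotype_id)), 0)
  }
})

test_that("a class with fewer than 2 clonotypes cannot be split", {
  ts <- toy_training_set(n_clono = 10)
  res <- ts$residuals[, 1:12]  # one reactive + one nonreactive clonotype
  lab <- c(rep(TRUE, 6), rep(FALSE, 6))
  cl <- rep(c("c01", "c02"), each = 6)
  ts1 <- training_set(res, colnames(res), lab, cl)
  expect_error(split_by_clonotype(ts1, 0.7, seed = 1),
               class = "reactcr_validation_error")
})

test_that("model fitting separates a separable toy and is reproducible", {
  ts <- toy_training_set(effect = 5)
  hp <- structure(list(learning_rate = 0.3, max_depth = 2,
                       n_estimators = 30L, subsample = 1,
                       colsample_bytree = 1, gamma = 0,
                       min_child_weight = 1, max_delta_step = 0,
                       alpha = 1e-3, lambda = 1, scale_pos_weight = 1),
                  class = "hyper_params")
  model <- fit_model(ts, hp, seed = 2)
  p <- predict_cell_probabilities(model, ts$residuals)
  expect_equal(roc_auc(p, ts$label), 1.0)

  model2 <- fit_model(ts, hp, seed = 2)
  p2 <- predict_cell_probabilities(model2, ts$residuals)
  expect_identical(p, p2)

  ts_one <- ts; ts_one$label <- rep(TRUE, length(ts$label))
  expect_error(fit_model(ts_one, hp), class = "reactcr_validation_error")
})

test_that("label permutation destroys held-out signal", {
  ts <- toy_training_set(n_clono = 20, cells_per = 10, effect = 5, seed = 6)
  set.seed(99)
  perm <- ts
  perm$label <- sample(ts$label)        # break label-feature coupling
  sp <- split_by_clonotype(perm, 0.7, seed = 3)
  hp <- structure(list(learning_rate = 0.1, max_depth = 3,
                       n_estimators = 50L, subsample = 1,
                       colsample_bytree = 1, gamma = 0,
                       min_child_weight = 1, max_delta_step = 0,
                       alpha = 1e-3, lambda = 1, scale_pos_weight = 1),
                  class = "hyper_params")
  model <- fit_model(sp$train, hp, seed = 3)
  p <- predict_cell_probabilities(model, sp$test$residuals)
  auc <- roc_auc(p, sp$test$label)
  expect_gte(auc, 0.35); expect_lte(auc, 0.65)
})

test_that("tuning reaches high CV AUC on separable data, errors under budget", {
  # every cell of a reactive clonotype expresses the program -> cell-level
  # labels are fully separable in feature space
  sim <- tiny_sim(seed = 7, log2fc = 3, cell_fraction = 1)
  ts <- sim_training_set(sim)
  hp <- tune_hyperparameters(ts, k = 3, budget = 10, seed = 7)
  expect_gte(attr(hp, "cv_auc"), 0.95)
  expect_error(tune_hyperparameters(ts, k = 3, budget = 5),
               class = "reactcr_validation_error")
})

test_that("a larger tuning budget never meaningfully hurts CV AUC", {
  sim <- tiny_sim(seed = 15, log2fc = 2)
  ts <- sim_training_set(sim)
  sub <- subset_training_set_test(ts, seq_along(ts$barcode) %% 2 == 0)
  a10 <- attr(tune_hyperparameters(sub, k = 3, budget = 10, seed = 2),
              "cv_auc")
  a25 <- attr(tune_hyperparameters(sub, k = 3, budget = 25, seed = 2),
              "cv_auc")
  expect_gte(a25, a10 - 0.02)
})

test_that("TreeSHAP equals exact subset-enumeration Shapley on stumps", {
  set.seed(1)
  n <- 60
  X <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, paste0("G", 1:3)))
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.1)
  dtr <- xgboost::xgb.DMatrix(X, label = y)
  bst <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = 1, eta = 0.3,
                  nthread = 1, base_score = 0),
    data = dtr, nrounds = 15)
  contrib <- predict(bst, dtr, predcontrib = TRUE)
  f <- function(M) predict(bst, xgboost::xgb.DMatrix(M, missing = NA))
  for (i in c(1, 7, 30)) {
    phi <- exact_shapley(f, X[i, ], X)
    expect_equal(unname(contrib[i, 1:3]), phi, tolerance = 1e-6)
  }
  # feature 3 is never split on -> exactly zero attribution everywhere
  expect_equal(max(abs(contrib[, 3])), 0)
})

test_that("SHAP ranking puts the driving gene first and ties break stably", {
  ts <- toy_training_set(effect = 6)
  hp <- structure(list(learning_rate = 0.3, max_depth = 2,
                       n_estimators = 20L, subsample = 1,
                       colsample_bytree = 1, gamma = 0,
                       min_child_weight = 1, max_delta_step = 0,
                       alpha = 1e-3, lambda = 1, scale_pos_weight = 1),
                  class = "hyper_params")
  model <- fit_model(ts, hp, seed = 1)
  rk <- shap_feature_ranking(model, ts$residuals)
  expect_equal(rk$gene[1], "G1")
  expect_equal(rk$rank, 1:4)
  expect_true(all(rk$importance >= 0))

  bad <- ts$residuals[1:2, , drop = FALSE]
  expect_error(shap_feature_ranking(model, bad),
               class = "reactcr_validation_error")
})

test_that("top-feature retraining restricts the feature space", {
  sim <- tiny_sim(seed = 8)
  ts <- sim_training_set(sim)
  hp <- tune_hyperparameters(ts, k = 3, budget = 10, seed = 8)
  model <- fit_model(ts, hp, seed = 8)
  rk <- shap_feature_ranking(model, ts$residuals)
  final <- retrain_top_features(ts, rk, n_top = 20, k = 3, budget = 10,
                                seed = 8)
  expect_length(final$features, 20)
  expect_equal(final$stage, "final")
  expect_setequal(final$features, rk$gene[1:20])

  all_feat <- retrain_top_features(ts, rk, n_top = nrow(rk), k = 3,
                                   budget = 10, seed = 8)
  expect_setequal(all_feat$features, model$features)

  expect_error(retrain_top_features(ts, rk, n_top = 1),
               class = "reactcr_validation_error")
})

test_that("prediction is equivariant, constant on zero input, imputes genes", {
  ts <- toy_training_set()
  hp <- structure(list(learning_rate = 0.3, max_depth = 2,
                       n_estimators = 20L, subsample = 1,
                       colsample_bytree = 1, gamma = 0,
                       min_child_weight = 1, max_delta_step = 0,
                       alpha = 1e-3, lambda = 1, scale_pos_weight = 1),
                  class = "hyper_params")
  model <- fit_model(ts, hp, seed = 5)
  p <- predict_cell_probabilities(model, ts$residuals)
  perm <- sample(ncol(ts$residuals))
  pp <- predict_cell_probabilities(model, ts$residuals[, perm])
  expect_identical(unname(pp), unname(p[perm]))

  zeros <- matrix(0, 4, 3, dimnames = list(paste0("G", 1:4),
                                           paste0("z", 1:3)))
  pz <- predict_cell_probabilities(model, zeros)
  expect_equal(length(unique(pz)), 1)

  # a sample missing half the model genes still predicts (imputed at 0)
  half <- ts$residuals[1:2, , drop = FALSE]
  expect_length(predict_cell_probabilities(model, half), ncol(ts$residuals))
  none <- matrix(0, 1, 2, dimnames = list("ZZZ", c("a", "b")))
  expect_error(predict_cell_probabilities(model, none),
               class = "reactcr_validation_error")
})

test_that("models round-trip through the JSON serialization", {
  ts <- toy_training_set()
  hp <- structure(list(learning_rate = 0.3, max_depth = 2,
                       n_estimators = 10L, subsample = 1,
                       colsample_bytree = 1, gamma = 0,
                       min_child_weight = 1, max_delta_step = 0,
                       alpha = 1e-3, lambda = 1, scale_pos_weight = 1),
                  class = "hyper_params")
  model <- fit_model(ts, hp, seed = 1)
  dir <- tempfile("model")
  write_model(model, dir)
  back <- read_model(dir)
  expect_equal(back$features, model$features)
  expect_equal(back$stage, model$stage)
  p1 <- predict_cell_probabilities(model, ts$residuals)
  p2 <- predict_cell_probabilities(back, ts$residuals)
  expect_equal(p1, p2, tolerance = 1e-7)

  expect_error(read_model(tempfile()), class = "reactcr_format_error")
})

test_that("class weighting helps on heavily imbalanced data", {
  # 1:75-style imbalance: few reactive cells in a sea of controls
  sim <- simulate_dataset(sim_config(
    n_genes = 80, n_background_cells = 1500, n_til_cells = 100,
    n_clonotypes = 10, frac_reactive_clonotypes = 0.4,
    program_log2fc = 2.5, n_program_genes = 5, n_donors = 6, seed = 21))
  ts <- sim_training_set(sim)
  sp <- split_by_clonotype(ts, 0.7, seed = 21)
  g_of <- function(tune_w) {
    hp <- tune_hyperparameters(sp$train, k = 3, budget = 10, seed = 21,
                               tune_scale_pos_weight = tune_w)
    model <- fit_model(sp$train, hp, seed = 21)
    p <- predict_cell_probabilities(model, sp$test$residuals)
    cc <- confusion(setNames(p > 0.5, names(p)),
                    setNames(sp$test$label, sp$test$barcode))
    g <- g_mean(cc)
    if (is.na(g)) 0 else g
  }
  expect_gte(g_of(TRUE), g_of(FALSE) - 0.02)
})
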