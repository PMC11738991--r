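# brute-force ssGSEA running sum for one cell (independent of the package's
# vectorized implementation)
brute_ssgsea <- function(expr, in_set, alpha = 0.25) {
  N <- length(expr)
  r <- rank(-expr, ties.method = "average")
  ord <- order(r)
  hit <- in_set[ord]
  w <- (N - r[ord] + 1)^alpha * hit
  p_hit <- cumsum(w) / sum(w)
  p_miss <- cumsum(!hit) / (N - sum(in_set))
  mean(p_hit - p_miss)
}

test_that("ssGSEA score matches a hand-rolled running sum on a 10-gene toy", {
  set.seed(4)
  m <- toy_counts(matrix(rpois(30, 5), 10, 3))
  sig <- gene_signature("s", positive = c("G02", "G05", "G07"))
  sc <- score_ssgsea(m, sig)
  x <- as.matrix(m)
  for (c in 1:3)
    expect_equal(sc$score[c],
                 brute_ssgsea(x[, c], rownames(m) %in% sig$positive),
                 tolerance = 1e-9)
})

test_that("ssGSEA is maximal when signature genes top the ranking", {
  n <- 200
  expr <- c(rep(1000L, 5), seq_len(n - 5))  # signature genes rank highest
  m <- toy_counts(matrix(expr, n, 1))
  sig <- gene_signature("s", positive = sprintf("G%02d", 1:5))
  top_score <- score_ssgsea(m, sig)$score
  # pushing the signature genes to the bottom flips the score low
  m2 <- toy_counts(matrix(c(rep(0L, 5), seq_len(n - 5) + 5L), n, 1))
  expect_gt(top_score, score_ssgsea(m2, sig)$score)
  expect_gt(top_score, 0.4)
  expect_lt(score_ssgsea(m2, sig)$score, 0)
})

test_that("uniformly interleaved signature genes score near zero", {
  n <- 1000
  expr <- seq_len(n)
  m <- toy_counts(matrix(rev(expr), n, 1))
  sig_genes <- sprintf("G%02d", seq(10, 1000, by = 100))  # every 100th rank
  m2 <- toy_counts(matrix(rev(expr), n, 1),
                   genes = sprintf("G%02d", 1:n))
  sig <- gene_signature("s", positive = sig_genes)
  expect_lt(abs(score_ssgsea(m2, sig)$score), 0.1)
})

test_that("ssGSEA and rank-U are invariant to monotone transforms", {
  set.seed(6)
  m <- toy_counts(matrix(rpois(200, 10), 50, 4))
  sig <- gene_signature("s", positive = sprintf("G%02d", c(3, 17, 41)))
  tm <- toy_counts(matrix(as.integer(as.matrix(m))^2, 50, 4))
  expect_equal(score_ssgsea(m, sig)$score, score_ssgsea(tm, sig)$score)
  expect_equal(score_rank_u(m, sig)$score, score_rank_u(tm, sig)$score)
})

test_that("additive score is the signed sum and is linear", {
  norm <- matrix(c(1, 2, 0.5, 0.5, 3, 1), 3, 2,
                 dimnames = list(c("P1", "P2", "N1"), c("b1", "b2")))
  sig <- gene_signature("s", positive = c("P1", "P2"), negative = "N1",
                        method = "additive")
  sc <- score_additive(norm, sig)
  expect_equal(sc$score, c(1 + 2 - 0.5, 0.5 + 3 - 1))
  expect_equal(sc$reactive_flag, c(TRUE, TRUE))
  expect_equal(score_additive(2 * norm, sig)$score, 2 * sc$score)

  # equal positive and negative sums -> 0, nonreactive under strict >
  norm0 <- matrix(c(1, 1, 2), 3, 1,
                  dimnames = list(c("P1", "P2", "N1"), "b1"))
  sc0 <- score_additive(norm0, sig)
  expect_equal(sc0$score, 0)
  expect_false(sc0$reactive_flag)

  # no negative genes -> positive sum
  sigp <- gene_signature("s", positive = c("P1", "P2"), method = "additive")
  expect_equal(score_additive(norm, sigp)$score, c(3, 3.5))
})

test_that("module score cancels when all genes are identically expressed", {
  norm <- matrix(1, 60, 5,
                 dimnames = list(sprintf("G%02d", 1:60), paste0("b", 1:5)))
  sig <- gene_signature("s", positive = c("G05", "G10"), method = "module")
  sc <- score_module(norm, sig, n_bins = 5, n_ctrl = 10, seed = 1)
  expect_equal(sc$score, rep(0, 5))
})

test_that("module score recovers a constructed uniform shift", {
  set.seed(10)
  n_genes <- 300
  norm <- matrix(rnorm(n_genes * 50, 1, 0.05), n_genes, 50,
                 dimnames = list(sprintf("G%03d", 1:n_genes),
                                 paste0("b", 1:50)))
  sig_genes <- sprintf("G%03d", 1:10)
  norm[sig_genes, ] <- norm[sig_genes, ] + 1
  sig <- gene_signature("s", positive = sig_genes, method = "module")
  # bin on pre-shift averages: use many bins so controls share baseline
  sc <- score_module(norm, sig, n_bins = 1, n_ctrl = 50, seed = 2)
  expect_true(all(abs(sc$score - 1) < 0.1))
})

test_that("module score is deterministic given the seed", {
  set.seed(12)
  norm <- matrix(rnorm(100 * 8), 100, 8,
                 dimnames = list(sprintf("G%03d", 1:100), paste0("b", 1:8)))
  sig <- gene_signature("s", positive = c("G010", "G050"), method = "module")
  s1 <- score_module(norm, sig, seed = 7, n_ctrl = 3)
  s2 <- score_module(norm, sig, seed = 7, n_ctrl = 3)
  expect_identical(s1, s2)
  # undersized bins fall back to replacement sampling with a warning
  expect_warning(score_module(norm, sig, seed = 7, n_ctrl = 20),
                 "replacement")
})

test_that("module score of a signature vs its own pool is centred at zero", {
  set.seed(13)
  norm <- matrix(rnorm(200 * 500, 2, 0.3), 200, 500,
                 dimnames = list(sprintf("G%03d", 1:200),
                                 paste0("b", 1:500)))
  sig <- gene_signature("s", positive = sprintf("G%03d", sample(200, 8)),
                        method = "module")
  sc <- score_module(norm, sig, n_bins = 4, n_ctrl = 30, seed = 3)
  expect_lt(abs(mean(sc$score)), 0.02)
})

test_that("rank-U score matches a brute-force Mann-Whitney U", {
  set.seed(14)
  m <- toy_counts(matrix(rpois(60, 20), 20, 3))
  pos <- c("G03", "G08", "G11", "G15", "G19")
  sig <- gene_signature("s", positive = pos, method = "rank_u")
  cap <- 15
  sc <- score_rank_u(m, sig, rank_cap = cap)
  x <- as.matrix(m)
  for (c in 1:3) {
    r <- pmin(rank(-x[, c], ties.method = "average"), cap)
    u <- sum(r[rownames(m) %in% pos]) - 5 * 6 / 2
    expect_equal(sc$score[c], min(max(1 - u / (5 * cap), 0), 1))
  }
})

test_that("rank-U spans its extremes", {
  n <- 50
  expr <- rev(seq_len(n))
  m <- toy_counts(matrix(expr, n, 1))
  top_sig <- gene_signature("s", positive = sprintf("G%02d", 1:5),
                            method = "rank_u")
  expect_equal(score_rank_u(m, top_sig, rank_cap = 30)$score, 1)
  bottom_sig <- gene_signature("s", positive = sprintf("G%02d", 46:50),
                               method = "rank_u")
  # all signature genes at/beyond the cap: score collapses to ~0
  expect_lt(score_rank_u(m, bottom_sig, rank_cap = 30)$score, 0.11)
})

test_that("cluster-based reactive flags follow the 0.95 quantile rule", {
  scores <- data.frame(barcode = paste0("b", 1:9),
                       score = c(9, 9.5, 10, 1, 1.2, 0.9, 1.1, 0.8, 1.0))
  clusters <- setNames(c(1, 1, 1, 2, 2, 2, 3, 3, 3), scores$barcode)
  out <- neotcr8_reactive_cells(scores, clusters)
  expect_true(all(out$reactive_flag[1:3]))
  expect_false(any(out$reactive_flag[4:9]))

  # all clusters equal: means tie at the quantile -> all flagged
  scores2 <- data.frame(barcode = paste0("b", 1:6), score = rep(2, 6))
  clusters2 <- setNames(rep(1:2, each = 3), scores2$barcode)
  out2 <- neotcr8_reactive_cells(scores2, clusters2)
  expect_true(all(out2$reactive_flag))

  expect_error(neotcr8_reactive_cells(scores, clusters[1:3]),
               class = "reactcr_validation_error")
})

test_that("reactive-cell fraction per clonotype is flagged / total", {
  scores <- data.frame(barcode = paste0("b", 1:6),
                       score = 1,
                       reactive_flag = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                         FALSE))
  ct <- data.frame(barcode = paste0("b", 1:6),
                   clonotype_id = c("c1", "c1", "c1", "c1", "c2", "c2"))
  s <- neotcr8_clonotype_score(scores, ct)
  expect_equal(s$mean_probability[s$clonotype_id == "c1"], 0.5)
  expect_equal(s$mean_probability[s$clonotype_id == "c2"], 0.0)
})

test_that("signature clonotype calls share the Fisher-Jenks layer", {
  # 6 clonotypes, bimodal means -> calls split at the natural break
  probs <- c(rep(0.1, 6), rep(0.85, 6))
  bc <- paste0("b", 1:12)
  scores <- data.frame(barcode = bc, score = probs)
  ct <- data.frame(barcode = bc,
                   clonotype_id = rep(sprintf("c%d", 1:6), each = 2))
  calls <- signature_clonotype_calls(scores, ct)
  expect_equal(sort(unique(calls$call[calls$mean_probability > 0.5])),
               "reactive")
  expect_equal(calls$threshold[1],
               brute_jenks2(calls$mean_probability))

  # flag-ratio path equals manual ratio + threshold computation
  scores$reactive_flag <- probs > 0.5
  fc <- signature_clonotype_calls(scores, ct, use_flags = TRUE)
  manual <- tapply(as.numeric(scores$reactive_flag),
                   ct$clonotype_id, mean)
  expect_equal(fc$mean_probability,
               as.numeric(manual[fc$clonotype_id]))

  one <- data.frame(barcode = "b1", score = 0.5)
  ct1 <- data.frame(barcode = "b1", clonotype_id = "c1")
  expect_error(signature_clonotype_calls(one, ct1),
               class = "reactcr_validation_error")
})
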