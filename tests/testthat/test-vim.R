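# vim_ranking: single trees, the three importance methods, tuning curves

test_that("fit_regression_tree matches exhaustive enumeration on a toy", {
  # 8 animals x 2 SNPs; best (snp, threshold) found by brute force
  X <- matrix(c(0L, 0L, 1L, 1L, 2L, 2L, 1L, 0L,
                2L, 0L, 1L, 2L, 0L, 1L, 2L, 0L), ncol = 2)
  y <- c(1.2, 0.9, 2.4, 2.1, 3.8, 4.1, 2.2, 1.1)
  bs <- oracle_best_split(X, y, 1:8)
  tr <- fit_regression_tree(X, y, min_node_size = 1, max_depth = 1)
  expect_identical(tr$var[1] + 1L, bs$var)
  expect_identical(tr$thr[1], bs$thr)
  expect_equal(tr$gain[1], bs$imp, tolerance = 1e-12)
})

test_that("single trees handle perfect predictors and constant response", {
  set.seed(21)
  X <- toy_dosage(40, 5, seed = 21)
  y <- as.numeric(X[, 1]) # response IS SNP 1's dosage
  tr <- fit_regression_tree(X, y, min_node_size = 1)
  expect_identical(tr$var[1], 0L) # root splits on SNP 1 (0-based)
  expect_equal(tr$pred, y, tolerance = 1e-12) # 3 classes, <= 2 levels, MSE 0

  trc <- fit_regression_tree(X, rep(3.5, 40))
  expect_identical(length(trc$var), 1L)
  expect_identical(trc$var[1], -1L)
  expect_identical(trc$value[1], 3.5)
})

test_that("deep trees match the pure-R oracle tree", {
  set.seed(22)
  X <- toy_dosage(60, 8, seed = 22)
  y <- rnorm(60) + X[, 3] * 0.8
  tr <- fit_regression_tree(X, y, min_node_size = 5)
  otr <- oracle_tree(X, y, 1:60, min_node = 5)
  expect_equal(tr$pred, otr$predict(X), tolerance = 1e-10)
})

test_that("rf_importance matches a straight-line oracle forest", {
  # mtry = m disables column sampling, so draws made in R fully determine
  # the forest and a naive reimplementation must agree exactly
  set.seed(23)
  X <- toy_dosage(20, 5, seed = 23)
  y <- rnorm(20) + X[, 2]
  g <- genotype_matrix(X, toy_map(5))
  pars <- rf_params(ntree = 3L, mtry = 5L, min_node_size = 5L, seed = 99)
  v <- rf_importance(g, y, pars)
  o <- oracle_rf(X, y, ntree = 3L, seed = 99)
  expect_equal(v$score, o$score, tolerance = 1e-10)
  expect_identical(attr(v, "trees_used"), o$cnt)
})

test_that("rf permutation importance separates signal from null SNPs", {
  set.seed(24)
  g <- toy_genotypes(150, 12, seed = 24, p = rep(0.4, 12))
  u <- g$dosage[, 1] * 1.0 # SNP 1 explains ~half the variance
  y <- u + rnorm(150, 0, sd(u))
  v <- rf_importance(g, y, rf_params(ntree = 500, mtry = 4, seed = 3))
  expect_identical(v$rank[1], 1L)
  # null SNPs: scores near zero (Monte-Carlo band over >= 500 trees),
  # and some fall below zero (negative importance is preserved)
  expect_lt(max(abs(v$score[-1])), 10)
  expect_lt(mean(v$score[-1]), 3)
  expect_lt(min(v$score), 0)
  # coverage: no more nonzero scores than SNPs ever used in the forest
  expect_lte(sum(v$score != 0), sum(attr(v, "trees_used") > 0))
})

test_that("single-QTL rank-1 recovery is stable across seeds", {
  hits <- sapply(1:5, function(s) {
    set.seed(s * 100)
    g <- toy_genotypes(120, 30, seed = s * 100, p = rep(0.4, 30))
    u <- g$dosage[, 7] * 1.0
    y <- u + rnorm(120, 0, sd(u))
    v <- rf_importance(g, y, rf_params(ntree = 300, mtry_frac = 0.2,
                                       seed = s))
    v$rank[7] == 1L
  })
  expect_gte(sum(hits), 5 * 0.95 - 1) # >= 95% of seeds (here: >= 4/5)
})

test_that("gbm_importance matches a stage-wise boosting oracle", {
  # fixture chosen so no two (snp, threshold) pairs induce the same row
  # partition: equal-gain ties would make split attribution depend on
  # floating-point summation order
  set.seed(25)
  X <- matrix(c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 1L, 2L, 0L,
                1L, 0L, 2L, 1L, 0L, 2L, 2L, 0L, 1L, 1L,
                2L, 1L, 0L, 2L, 1L, 0L, 0L, 2L, 1L, 1L), ncol = 3)
  y <- rnorm(10) + 0.6 * X[, 2]
  g <- genotype_matrix(X, toy_map(3))
  pars <- boost_params(ntree = 3L, learning_rate = 0.1, max_depth = 2L,
                       min_samples_leaf = 1L, subsample = 1, seed = 1)
  v <- gbm_importance(g, y, pars)
  o <- oracle_gbm(X, y, ntree = 3L, lr = 0.1, max_depth = 2L, min_leaf = 1L)
  expect_equal(v$score, o$influence, tolerance = 1e-10)
  expect_equal(attr(v, "fitted"), o$fitted, tolerance = 1e-10)
  expect_true(all(v$score >= 0))
})

test_that("gbm influence concentrates on a single linear predictor", {
  set.seed(26)
  g <- toy_genotypes(80, 10, seed = 26, p = rep(0.4, 10))
  y <- 2 * g$dosage[, 1] + rnorm(80, 0, 1e-3)
  v <- gbm_importance(g, y, boost_params(ntree = 50, max_depth = 1,
                                         min_samples_leaf = 5, seed = 1))
  expect_gt(v$score[1] / sum(v$score), 0.99)
})

test_that("gbm on pure noise spreads influence and does not improve held-out MSE", {
  set.seed(27)
  g <- toy_genotypes(100, 20, seed = 27)
  y <- rnorm(100)
  v <- gbm_importance(g, y, boost_params(ntree = 100, seed = 5))
  expect_lt(max(v$score) / sum(v$score), 0.3)
  # held-out MSE at many stages is no better than at few
  tc <- tuning_curve(g, y, "gbm",
                     data.frame(ntree = c(20L, 200L), learning_rate = 0.1,
                                min_samples_leaf = 5L),
                     seed = 4)
  expect_gte(tc$grid$mean_mse[2], tc$grid$mean_mse[1] * 0.95)
})

test_that("second-order gain formula and its reductions", {
  # plug-in example: G_L=-3, H_L=2, G_R=-1, H_R=3, lambda=1
  expect_equal(xgb_split_gain(-3, 2, -1, 3, lambda = 1),
               0.5 * (9 / 3 + 1 / 4 - 16 / 6), tolerance = 1e-12)
  expect_equal(xgb_split_gain(-3, 2, -1, 3, lambda = 1, gamma = 0.1),
               0.5 * (9 / 3 + 1 / 4 - 16 / 6) - 0.1, tolerance = 1e-12)

  # lambda = 0, gamma = 0, depth 1, one stage, lr 1: the second-order
  # booster reduces to the plain variance-reduction split with mean leaves
  set.seed(28)
  X <- toy_dosage(50, 6, seed = 28)
  y <- rnorm(50) + X[, 4]
  g <- genotype_matrix(X, toy_map(6))
  v <- xgb_importance(g, y, boost_params(ntree = 1L, learning_rate = 1,
                                         max_depth = 1L,
                                         min_samples_leaf = 1L,
                                         reg_lambda = 0, reg_gamma = 0,
                                         seed = 1))
  tr <- fit_regression_tree(X, y, min_node_size = 1, max_depth = 1)
  expect_identical(which.max(v$score) - 1L, tr$var[1])
  expect_equal(attr(v, "fitted"), tr$pred, tolerance = 1e-10)
})

test_that("xgb gain scores normalize to one and params are validated", {
  set.seed(29)
  g <- toy_genotypes(60, 8, seed = 29)
  y <- rnorm(60) + g$dosage[, 2]
  v <- xgb_importance(g, y, boost_params(ntree = 20, seed = 2))
  expect_equal(sum(v$score), 1, tolerance = 1e-12)
  expect_true(all(v$score >= 0))
  expect_error(boost_params(learning_rate = 0), "learning_rate")
  expect_error(boost_params(reg_lambda = -1), "reg_lambda")
})

test_that("same seed reproduces every method exactly", {
  g <- toy_genotypes(60, 15, seed = 30)
  y <- rnorm(60) + g$dosage[, 5]
  for (fitfun in list(
    function() rf_importance(g, y, rf_params(ntree = 30, seed = 7)),
    function() gbm_importance(g, y, boost_params(ntree = 20, seed = 7,
                                                 subsample = 0.8)),
    function() xgb_importance(g, y, boost_params(ntree = 20, seed = 7,
                                                 subsample = 0.8)))) {
    expect_identical(fitfun()$score, fitfun()$score)
  }
})

test_that("tuning curve ordering and plateau detection", {
  expect_identical(find_plateau(c(5, 3, 1, 1.001, 1.0005), 0.02), 3L)
  expect_identical(find_plateau(7), 1L)

  # single-marker trees (mtry = 1) dominate tuned mtry (0.1 m) in
  # forest-aggregated OOB MSE
  set.seed(31)
  sim <- simulate_cohort(sim_config(n_animals = 200L, m_snps = 200L,
                                    n_qtl = 5L, h2_true = 0.5, seed = 31))
  p <- adjust_phenotypes(sim$phenotypes)
  tc <- tuning_curve(sim$genotypes, p$y_adjusted, "rf",
                     data.frame(ntree = 200L, mtry = c(1L, 20L)), seed = 9)
  expect_gt(tc$grid$mean_mse[1], tc$grid$mean_mse[2])
  expect_error(tuning_curve(sim$genotypes, p$y_adjusted, "rf",
                            data.frame()[0, ]), "non-empty")
})

test_that("top-ranked SNPs capture most of the QTL variance", {
  # the attainable desk-scale analogue of low-density screening power:
  # N(0,1) effect sizes leave some QTLs undetectable as individual loci,
  # but the top-3k set captures the bulk of the additive VARIANCE
  share <- sapply(1:2, function(s) {
    sim <- simulate_cohort(sim_config(n_animals = 800L, m_snps = 1500L,
                                      n_qtl = 20L, h2_true = 0.3, seed = s))
    p <- adjust_phenotypes(sim$phenotypes)
    v <- gbm_importance(sim$genotypes, p$y_adjusted,
                        boost_params(ntree = 100, seed = s))
    top <- top_k(v, 60)$snp_ids
    af <- allele_freq(sim$genotypes)[sim$truth$qtl_ids]
    vshare <- sim$truth$qtl_effects^2 * 2 * af * (1 - af)
    sum(vshare[sim$truth$qtl_ids %in% top]) / sum(vshare)
  })
  expect_gte(min(share), 0.7)
})
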