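# reml_gblup: restricted likelihood, variance components, GEBV prediction

make_reml_fixture <- function(n, m, h2, seed, n_groups = 3L) {
  sim <- simulate_cohort(sim_config(n_animals = n, m_snps = m,
                                    n_qtl = max(5L, m %/% 20L),
                                    h2_true = h2, n_groups = n_groups,
                                    seed = seed))
  p <- sim$phenotypes
  G <- suppressWarnings(build_vanraden(sim$genotypes)) # small n: monomorphics drop
  spec <- mixed_model_spec(setNames(p$y_raw, p$animal_id),
                           build_fixed_design(p), G)
  list(sim = sim, p = p, G = G, spec = spec)
}

test_that("eigen-path restricted likelihood equals the direct matrix form", {
  fx <- make_reml_fixture(60, 300, 0.4, seed = 61)
  H <- fx$G$matrix
  y <- as.numeric(fx$spec$y)
  X <- fx$spec$X
  set.seed(62)
  for (i in 1:20) {
    sa <- runif(1, 1, 400)
    se <- runif(1, 10, 800)
    expect_equal(reml_loglik(fx$spec, sa, se),
                 reml_ll_direct(y, X, H, sa, se), tolerance = 1e-8)
  }
})

test_that("REML optimum matches a 2-D grid search on a small fixture", {
  # intercept-only design keeps the direct-solve oracle well conditioned
  fx <- make_reml_fixture(30, 200, 0.5, seed = 63)
  spec <- mixed_model_spec(fx$spec$y, matrix(1, 30, 1), fx$G)
  vc <- fit_reml(spec)
  y <- as.numeric(spec$y)
  X <- spec$X
  H <- fx$G$matrix
  vy <- var(y)
  # coarse grid, then exhaustive refinement around the coarse argmax
  sa_g <- seq(vy * 0.01, vy * 2, length.out = 40)
  se_g <- seq(vy * 0.01, vy * 2, length.out = 40)
  ll <- outer(sa_g, se_g, Vectorize(function(a, e)
    reml_ll_direct(y, X, H, a, e)))
  ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  step <- sa_g[2] - sa_g[1]
  sa_f <- seq(max(1e-6, sa_g[ix[1]] - step), sa_g[ix[1]] + step,
              length.out = 81)
  se_f <- seq(max(1e-6, se_g[ix[2]] - step), se_g[ix[2]] + step,
              length.out = 81)
  llf <- outer(sa_f, se_f, Vectorize(function(a, e)
    reml_ll_direct(y, X, H, a, e)))
  ixf <- which(llf == max(llf), arr.ind = TRUE)[1, ]
  # relative agreement: grid spacing bounds the attainable precision
  expect_equal(vc$sigma2_a, sa_f[ixf[1]],
               tolerance = (sa_f[2] - sa_f[1]) / vc$sigma2_a + 1e-3)
  expect_equal(vc$sigma2_e, se_f[ixf[2]],
               tolerance = (se_f[2] - se_f[1]) / vc$sigma2_e + 1e-3)
  expect_gte(vc$loglik_reml, max(llf) - 1e-6)
})

test_that("null heritability is recovered as near-zero", {
  hits <- sapply(1:5, function(s) {
    g <- simulate_genotypes(sim_config(n_animals = 500L, m_snps = 800L,
                                       n_qtl = 0L, h2_true = 0, seed = s))
    set.seed(s + 1000)
    y <- setNames(rnorm(500, 0, 10), rownames(g$dosage))
    vc <- fit_reml(mixed_model_spec(y, matrix(1, 500, 1),
                                    build_vanraden(g)))
    vc$h2 < 0.05
  })
  expect_gte(sum(hits), 4) # spec: >= 90% of seeds; 5 fixed seeds here
})

test_that("identity GRM is flagged as non-identifiable", {
  set.seed(64)
  y <- setNames(rnorm(40), sprintf("A%03d", 1:40))
  vc <- fit_reml(mixed_model_spec(y, matrix(1, 40, 1), manual_grm(diag(40))))
  expect_false(vc$converged)
  expect_match(vc$flags, "not_identifiable")
  expect_true(is.na(vc$sigma2_a))
  expect_true(is.finite(vc$sigma2_p)) # the total is still identified
})

test_that("estimates are invariant to the fixed-effect parameterization", {
  fx <- make_reml_fixture(120, 400, 0.4, seed = 65)
  vc1 <- fit_reml(fx$spec)
  p2 <- fx$p
  p2$group <- factor(p2$group, levels = rev(sort(unique(p2$group))))
  spec2 <- mixed_model_spec(setNames(p2$y_raw, p2$animal_id),
                            build_fixed_design(p2), fx$G)
  vc2 <- fit_reml(spec2)
  expect_equal(vc1$sigma2_a, vc2$sigma2_a, tolerance = 1e-6)
  expect_equal(vc1$loglik_reml, vc2$loglik_reml, tolerance = 1e-8)
})

test_that("heritability recovery across levels, with honest standard errors", {
  # deterministic under fixed seeds; desk-scale version of the
  # parameter-recovery property (10 replicates per level)
  for (h2t in c(0.125, 0.3, 0.5)) {
    fits <- lapply(1:10, function(s)
      fit_reml(make_reml_fixture(500, 1500, h2t, seed = s + 70)$spec))
    h2s <- vapply(fits, `[[`, numeric(1), "h2")
    expect_lt(abs(mean(h2s) - h2t), 0.05)
    ses <- vapply(fits, `[[`, numeric(1), "se_h2")
    # reported SEs agree with the empirical spread within a factor ~2
    expect_gt(mean(ses, na.rm = TRUE) / sd(h2s), 0.5)
    expect_lt(mean(ses, na.rm = TRUE) / sd(h2s), 2.5)
  }
})

test_that("GEBV limits: total shrinkage, vanishing shrinkage, clones", {
  fx <- make_reml_fixture(80, 300, 0.4, seed = 66)
  # sigma2_a = 0 -> every GEBV is 0
  gb0 <- predict_gebv(fx$spec, manual_vc(0, 1))
  expect_true(all(gb0$gebv == 0))

  # h2 -> 1: GEBVs of phenotyped animals approach the corrected phenotype
  fx1 <- make_reml_fixture(200, 400, 0.98, seed = 67)
  vc1 <- fit_reml(fx1$spec)
  gb1 <- predict_gebv(fx1$spec, vc1)
  pc <- adjust_phenotypes(fx1$p)
  expect_gt(cor(gb1$gebv[match(pc$animal_id, gb1$animal_id)],
                pc$y_corrected), 0.97)

  # clone pair with one member unphenotyped receives the same GEBV
  d <- toy_dosage(25, 200, seed = 68)
  d <- rbind(d, CLONE = d[25, ])
  rownames(d)[25] <- "ORIG"
  g <- genotype_matrix(d, toy_map(200))
  G <- build_vanraden(g)
  set.seed(69)
  u <- rnorm(26, 0, 3)
  y <- setNames(u + rnorm(26), rownames(d))
  spec <- mixed_model_spec(y, matrix(1, 26, 1), G)
  vc <- fit_reml(spec)
  gb <- predict_gebv(spec, vc, unphenotyped = "CLONE")
  expect_equal(gb$gebv[gb$animal_id == "CLONE"],
               gb$gebv[gb$animal_id == "ORIG"], tolerance = 1e-8)
  expect_error(predict_gebv(spec, vc, unphenotyped = rownames(d)), "all")

  # reliabilities are sane when requested
  gbr <- predict_gebv(spec, vc, reliability = TRUE)
  expect_true(all(gbr$reliability >= 0 & gbr$reliability <= 1))
})

test_that("variance_share reports the Table-4-style percentage", {
  vc_all <- manual_vc(75, 525)
  expect_equal(variance_share(vc_all, vc_all), 100)
  expect_equal(variance_share(manual_vc(0, 600), vc_all), 0)
  expect_error(variance_share(vc_all, manual_vc(0, 600)), "undefined|zero")

  # panel with all QTLs ~ all SNPs; panel with none falls far short
  sim <- simulate_cohort(sim_config(n_animals = 500L, m_snps = 800L,
                                    n_qtl = 100L, h2_true = 0.4, seed = 70))
  p <- sim$phenotypes
  y <- setNames(p$y_raw, p$animal_id)
  X <- build_fixed_design(p)
  fit_pan <- function(panel)
    fit_reml(mixed_model_spec(y, X, build_vanraden(sim$genotypes, panel)))
  vc_all2 <- fit_pan(NULL)
  qtl_pan <- snp_panel("qtl", sim$truth$qtl_ids, "vim_topk")
  null_ids <- setdiff(sim$genotypes$map$snp_id, sim$truth$qtl_ids)[1:100]
  null_pan <- snp_panel("null", null_ids, "vim_topk")
  expect_gt(variance_share(fit_pan(qtl_pan), vc_all2), 70)
  expect_lt(variance_share(fit_pan(null_pan), vc_all2), 30)
})

test_that("GEBV accuracy grows with training cohort size", {
  acc <- sapply(c(200L, 500L, 1000L), function(n) {
    fx <- make_reml_fixture(n, 800, 0.4, seed = 71)
    vc <- fit_reml(fx$spec)
    gb <- predict_gebv(fx$spec, vc)
    cor(gb$gebv, fx$sim$truth$true_breeding_values[gb$animal_id])
  })
  expect_true(all(diff(acc) > 0))
})
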