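# data_io: format dialects, QC, phenotype pre-adjustment

test_that("VCF round trip and dosage coding", {
  skip_if_not_installed("VariantAnnotation")
  g <- toy_genotypes(10, 20, seed = 2)
  g$dosage[3, 5] <- NA # a missing call survives the round trip
  f <- tempfile(fileext = ".vcf")
  write_genotypes(g, f, "vcf")
  g2 <- suppressWarnings(read_genotypes(f, "vcf"))
  expect_identical(unname(g2$dosage), unname(g$dosage))
  expect_identical(rownames(g2$dosage), rownames(g$dosage))
  expect_identical(g2$map$pos_bp, g$map$pos_bp)

  # one sample, one het site -> 1x1 [[1]]
  f1 <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=1>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/1"), f1)
  g1 <- read_genotypes(f1, "vcf")
  expect_equal(unname(g1$dosage), matrix(1L, 1, 1))

  # multi-allelic site rejected with its id
  fm <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=1>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "1\t100\trsX\tA\tG,T\t.\t.\t.\tGT\t0/1"), fm)
  expect_error(read_genotypes(fm, "vcf"), "rsX")
})

test_that("PLINK .raw dialect", {
  f <- tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE snp1_A snp2_B snp3_A",
               "F1 A1 0 0 1 -9 0 2 NA"), f)
  g <- read_genotypes(f, "plink_raw")
  expect_identical(as.vector(g$dosage), c(0L, 2L, NA))
  expect_identical(rownames(g$dosage), "A1")
  expect_identical(g$map$snp_id, c("snp1", "snp2", "snp3"))
  expect_identical(g$map$allele_alt, c("A", "B", "A"))
})

test_that("tsv and plink_raw round trips preserve dosage, ids and map", {
  g <- toy_genotypes(10, 50, seed = 3)
  g$dosage[cbind(c(1, 7), c(10, 42))] <- NA
  for (fmt in c("tsv", "plink_raw")) {
    f <- tempfile()
    write_genotypes(g, f, fmt)
    g2 <- read_genotypes(f, fmt, map = g$map)
    expect_identical(g2$dosage, g$dosage, label = fmt)
    expect_identical(g2$map, g$map, label = fmt)
  }
  # snp map round trip
  fmap <- tempfile()
  write_snp_map(g$map, fmap)
  expect_equal(read_snp_map(fmap), g$map)
})

test_that("qc_filter enforces the MAF floor and full-genotype rule", {
  set.seed(42)
  # 3 SNPs with MAFs 0.30 / 0.005 / 0.30 on 100 animals
  d <- cbind(rbinom(100, 2, 0.3), c(1L, rep(0L, 99)), rbinom(100, 2, 0.3))
  d[, 1] <- pmax(d[, 1], c(1L, rep(0L, 99)))   # guarantee polymorphic
  d[, 3] <- pmax(d[, 3], c(1L, rep(0L, 99)))
  g <- genotype_matrix(d, toy_map(3))
  res <- qc_filter(g, maf_min = 0.01)
  expect_identical(res$removed$snp_id, "SNP002")
  expect_identical(res$removed$reason, "maf_below_min")
  expect_identical(n_snps(res$genotypes), 2L)
  expect_identical(n_animals(res$genotypes), 100L)

  # common SNP with one missing call still removed
  d2 <- cbind(rbinom(50, 2, 0.4), rbinom(50, 2, 0.4))
  d2[, 1] <- pmax(d2[, 1], c(1L, rep(0L, 49)))
  d2[, 2] <- pmax(d2[, 2], c(1L, rep(0L, 49)))
  d2[5, 2] <- NA
  res2 <- qc_filter(genotype_matrix(d2, toy_map(2)), 0.01)
  expect_identical(res2$removed$snp_id, "SNP002")
  expect_match(res2$removed$reason, "missing_calls")

  # exact ties at maf_min are retained (removal rule is MAF < floor)
  d3 <- cbind(c(rep(1L, 2), rep(0L, 98)), rbinom(100, 2, 0.5)) # maf exactly 0.01
  g3 <- genotype_matrix(d3, toy_map(2))
  expect_identical(n_snps(qc_filter(g3, 0.01)$genotypes), 2L)

  # all SNPs removed -> error
  mono <- genotype_matrix(matrix(0L, 10, 2), toy_map(2))
  expect_error(qc_filter(mono, 0.01), "every SNP")
})

test_that("qc_filter is idempotent", {
  g <- toy_genotypes(80, 40, seed = 4, p = runif(40, 0.005, 0.5))
  g$dosage[sample(length(g$dosage), 20)] <- NA
  once <- qc_filter(g, 0.05)$genotypes
  twice <- qc_filter(once, 0.05)
  expect_identical(twice$genotypes$dosage, once$dosage)
  expect_identical(nrow(twice$removed), 0L)
})

test_that("adjust_phenotypes removes group and age effects", {
  # no-covariate case: one group, constant age -> y_adjusted == y_raw
  p0 <- toy_phenotypes(30, seed = 5, n_groups = 1)
  p0$age_days <- 365L
  a0 <- adjust_phenotypes(p0)
  expect_equal(a0$y_adjusted, p0$y_raw)
  expect_equal(mean(a0$y_corrected), 0)

  # perfect fit: y = 2 * age exactly -> residuals all zero
  p1 <- toy_phenotypes(30, seed = 6, n_groups = 1)
  p1$y_raw <- 2 * p1$age_days
  a1 <- adjust_phenotypes(p1)
  expect_equal(a1$y_corrected, rep(0, 30), tolerance = 1e-10)
  expect_equal(a1$y_adjusted, rep(mean(p1$y_raw), 30), tolerance = 1e-8)

  # known group contrasts {+10, -10} recovered within OLS standard error
  set.seed(7)
  n <- 400
  grp <- sample(c("G1", "G2"), n, replace = TRUE)
  age <- sample(323:400, n, replace = TRUE)
  eff <- c(G1 = 10, G2 = -10)
  y <- 200 + eff[grp] + 0.5 * age + rnorm(n, 0, 5)
  p2 <- phenotype_table(data.frame(animal_id = sprintf("A%03d", 1:n),
                                   y_raw = y, group = grp, age_days = age))
  a2 <- adjust_phenotypes(p2)
  fit <- attr(a2, "fit")
  est_contrast <- coef(fit)[["grpG2"]]
  se <- summary(fit)$coefficients["grpG2", "Std. Error"]
  expect_lt(abs(est_contrast - (-20)), 3 * se)
  expect_lt(abs(coef(fit)[["age"]] - 0.5), 0.1)

  # residuals orthogonal to each fixed-effect column
  Xf <- model.matrix(~ factor(grp) + age)
  expect_lt(max(abs(crossprod(Xf, a2$y_corrected))), 1e-6)

  # invariant to the reference-group choice
  p3 <- p2
  p3$group <- factor(p3$group, levels = c("G2", "G1"))
  a3 <- adjust_phenotypes(p3)
  expect_equal(a3$y_corrected, a2$y_corrected, tolerance = 1e-8)
})

test_that("singleton contemporary groups are flagged but estimated", {
  p <- toy_phenotypes(20, seed = 8, n_groups = 2)
  p$group[1] <- "LONER"
  expect_warning(adjust_phenotypes(p), "LONER")
})

test_that("phenotype table io round trips", {
  p <- adjust_phenotypes(toy_phenotypes(15, seed = 9))
  f <- tempfile()
  write_phenotypes(p, f)
  p2 <- read_phenotypes(f)
  expect_equal(p2$y_corrected, p$y_corrected)
  expect_identical(p2$animal_id, p$animal_id)
})
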