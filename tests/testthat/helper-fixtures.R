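# Programmatic fixtures (no data files): small dosage matrices, phenotype
# tables and cohorts built in code under fixed seeds.

toy_dosage <- function(n, m, seed = 1, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.5)
  d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
  rownames(d) <- sprintf("A%03d", seq_len(n))
  d
}

toy_genotypes <- function(n, m, seed = 1, p = NULL) {
  genotype_matrix(toy_dosage(n, m, seed, p), toy_map(m))
}

toy_map <- function(m, n_chrom = 2L) {
  chrom <- sort(rep(seq_len(n_chrom), length.out = m))
  pos <- unlist(lapply(split(seq_len(m), chrom), seq_along)) * 1000L
  data.frame(snp_id = sprintf("SNP%03d", seq_len(m)),
             chrom = as.character(chrom), pos_bp = pos,
             allele_ref = "A", allele_alt = "B", stringsAsFactors = FALSE)
}

toy_phenotypes <- function(n, seed = 1, n_groups = 3L) {
  set.seed(seed)
  phenotype_table(data.frame(
    animal_id = sprintf("A%03d", seq_len(n)),
    y_raw = rnorm(n, 200, 20),
    group = sample(sprintf("CG%d", seq_len(n_groups)), n, replace = TRUE),
    age_days = sample(323:400, n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# A vim_table with prescribed scores on a toy map.
toy_vim <- function(scores, method = "rf_permutation", n_chrom = 2L) {
  vim_table(method, toy_map(length(scores), n_chrom), scores)
}

# grm object wrapping a given matrix (for diagnostics tests).
manual_grm <- function(M, name = "manual") {
  ids <- sprintf("A%03d", seq_len(nrow(M)))
  dimnames(M) <- list(ids, ids)
  structure(list(matrix = M, animal_ids = ids, m_snps = NA_integer_,
                 denominator = NA_real_, allele_freqs = NULL,
                 ridge_used = 0, name = name), class = "grm")
}

manual_vc <- function(sigma2_a, sigma2_e) {
  structure(list(sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 sigma2_p = sigma2_a + sigma2_e,
                 h2 = sigma2_a / (sigma2_a + sigma2_e),
                 se_sigma2_a = NA_real_, se_sigma2_e = NA_real_,
                 se_h2 = NA_real_, loglik_reml = NA_real_,
                 converged = TRUE, boundary = FALSE, flags = "",
                 lambda = sigma2_a / sigma2_e),
            class = "variance_components")
}
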