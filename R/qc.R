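#' SNP quality control: MAF floor and full-genotype requirement
#'
#' Removes SNPs whose minor allele frequency (computed from observed calls
#' only) is below `maf_min`, and SNPs with any missing call — tree-ensemble
#' rankers require complete genotypes. SNPs at exactly `maf_min` are
#' retained. The animal set is unchanged and the operation is idempotent.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min MAF floor in `[0, 0.5]`; default 0.01.
#' @return list with elements `genotypes` (filtered [genotype_matrix()])
#'   and `removed` (data.frame `snp_id`, `reason`; reasons are
#'   `missing_calls` and/or `maf_below_min`, comma-joined).
#' @export
qc_filter <- function(g, maf_min = 0.01) {
  validate_genotype_matrix(g)
  assert_scalar_num(maf_min, "maf_min", 0, 0.5)
  d <- g$dosage
  nmiss <- colSums(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[!is.finite(maf)] <- 0 # all-missing column
  low <- maf < maf_min
  has_miss <- nmiss > 0L
  drop <- low | has_miss
  if (all(drop)) stop_("qc_filter removed every SNP (maf_min = ", maf_min, ")")
  reason <- character(sum(drop))
  reason[] <- ""
  dm <- has_miss[drop]
  dl <- low[drop]
  reason[dm & dl] <- "missing_calls,maf_below_min"
  reason[dm & !dl] <- "missing_calls"
  reason[!dm & dl] <- "maf_below_min"
  removed <- data.frame(snp_id = g$map$snp_id[drop], reason = reason,
                        stringsAsFactors = FALSE)
  keep <- which(!drop)
  out <- genotype_matrix(d[, keep, drop = FALSE], g$map[keep, , drop = FALSE])
  list(genotypes = out, removed = removed)
}

#' Pre-adjust phenotypes for contemporary group and age
#'
#' Fits ordinary least squares of the raw trait on contemporary-group
#' indicators (treatment contrasts) and linear age, then stores two
#' residual-based phenotypes: `y_corrected` (the mean-zero residual,
#' used when scoring prediction accuracy) and `y_adjusted` (residual plus
#' the grand mean, the machine-learning input). Both are the trait with
#' fixed effects removed; they differ only by centering.
#'
#' @param p a [phenotype_table()] with `y_raw`, `group`, `age_days`.
#' @return the table with `y_adjusted` and `y_corrected` columns added and
#'   the fitted model stored in attribute `"fit"`.
#' @export
adjust_phenotypes <- function(p) {
  p <- phenotype_table(p)
  if (anyNA(p$y_raw) || anyNA(p$group) || anyNA(p$age_days))
    stop_("phenotype table has missing y_raw/group/age_days")
  grp <- factor(p$group)
  singletons <- names(which(table(grp) == 1L))
  if (length(singletons))
    warning("contemporary group(s) with a single record: ",
            paste(singletons, collapse = ", "),
            " (group effect still estimated)", call. = FALSE)
  dat <- data.frame(y = p$y_raw, grp = grp, age = as.numeric(p$age_days))
  form <- if (nlevels(grp) > 1L) y ~ grp + age else y ~ age
  if (length(unique(dat$age)) == 1L)
    form <- if (nlevels(grp) > 1L) y ~ grp else y ~ 1
  fit <- lm(form, data = dat)
  res <- residuals(fit)
  p$y_corrected <- as.numeric(res)
  p$y_adjusted <- as.numeric(res) + mean(p$y_raw)
  attr(p, "fit") <- fit
  p
}
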