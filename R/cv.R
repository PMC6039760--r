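#' Cross-validation configuration
#'
#' @param n_folds number of folds (>= 2).
#' @param seed RNG seed for the fold split.
#' @param scheme `"random"` (seeded permutation into near-equal folds) or
#'   `"family_based"` (whole sire families kept together).
#' @return list of class `cv_config`.
#' @export
cv_config <- function(n_folds = 5L, seed = 1L,
                      scheme = c("random", "family_based")) {
  scheme <- match.arg(scheme)
  stopifnot(n_folds >= 2L)
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed),
                 scheme = scheme), class = "cv_config")
}

#' Assign animals to cross-validation folds
#'
#' Random scheme: a seeded permutation split into `n_folds` near-equal
#' parts (sizes differ by at most 1; e.g. 996 animals in 5 folds give
#' 200/199/199/199/199). Family scheme: whole families are assigned
#' greedily, largest first, to the currently smallest fold, so no family
#' spans a training/validation boundary.
#'
#' @param animal_ids character vector.
#' @param cfg a [cv_config()].
#' @param families named vector (animal id -> family label); required for
#'   the family scheme.
#' @return named integer vector of fold labels `1..n_folds`.
#' @export
make_folds <- function(animal_ids, cfg = cv_config(), families = NULL) {
  n <- length(animal_ids)
  k <- cfg$n_folds
  if (k > n) stop_("more folds than animals")
  set.seed(cfg$seed)
  if (cfg$scheme == "random") {
    perm <- sample.int(n)
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    fold <- integer(n)
    fold[perm] <- rep(seq_len(k), times = sizes)
  } else {
    if (is.null(families)) stop_("family_based scheme requires family labels")
    fam <- families[animal_ids]
    if (anyNA(fam)) stop_("missing family label for some animals")
    tab <- sort(table(fam), decreasing = TRUE)
    fam_order <- sample(names(tab)) # shuffle ties deterministically
    fam_order <- fam_order[order(-tab[fam_order])]
    fsize <- integer(k)
    fassign <- integer(length(fam_order))
    names(fassign) <- fam_order
    for (f in fam_order) {
      i <- which.min(fsize)
      fassign[f] <- i
      fsize[i] <- fsize[i] + tab[f]
    }
    fold <- unname(fassign[fam])
  }
  setNames(as.integer(fold), animal_ids)
}

#' Cross-validated genomic prediction accuracy for one SNP panel
#'
#' Per fold: the fold's phenotypes are masked, the single-GRM model (raw
#' phenotype with contemporary group and age as fixed effects) is fitted
#' by REML on the remaining animals, GEBVs are predicted for the masked
#' animals, and the fold accuracy is
#' `cor(GEBV, y_corrected) / sqrt(h2_used)` where `y_corrected` is the
#' fixed-effect-corrected phenotype. `h2_used` defaults to the panel's
#' REML heritability on the full cohort (one value per panel); set
#' `h2 = "per_fold"` for the per-fold training estimate, or pass a number.
#'
#' @param g validation-cohort [genotype_matrix()] (complete).
#' @param p [phenotype_table()] for the same animals; `y_corrected` is
#'   computed via [adjust_phenotypes()] if absent.
#' @param panel a [snp_panel()] (`NULL` = all SNPs).
#' @param cfg a [cv_config()].
#' @param h2 `"panel"`, `"per_fold"`, or a positive number.
#' @param h2_floor lower bound applied to the accuracy denominator, so
#'   near-zero heritability estimates (e.g. under a permutation null)
#'   cannot blow the statistic up. Rescales but never re-centers.
#' @param min_h2_train folds whose training heritability falls at or below
#'   this value are skipped with a warning; set to 0 to keep
#'   boundary-heritability folds (used by permutation-null checks, where
#'   skipping would condition on the noise).
#' @param use_adjusted fit the model on the pre-adjusted phenotype with an
#'   intercept-only design instead of the raw phenotype + fixed effects.
#' @param folds optional precomputed [make_folds()] assignment (enables
#'   fold reuse across panels).
#' @return list of class `cv_result`: `panel_name`, `fold_accuracies`,
#'   `mean_accuracy`, `sd_accuracy`, `h2_used`, `fold_hash`, `gebv` (the
#'   masked-fold predictions, one per animal), `vc_full`.
#' @export
cv_accuracy <- function(g, p, panel = NULL, cfg = cv_config(),
                        h2 = c("panel", "per_fold"), h2_floor = 0.05,
                        min_h2_train = 0.01, use_adjusted = FALSE,
                        folds = NULL) {
  if (!is.numeric(h2)) h2 <- match.arg(h2)
  p <- phenotype_table(p)
  if (is.null(p$y_corrected)) p <- adjust_phenotypes(p)
  ids <- rownames(g$dosage)
  p <- p[match(ids, p$animal_id), , drop = FALSE]
  if (anyNA(p$animal_id)) stop_("phenotypes missing for some genotyped animals")

  G <- build_vanraden(g, panel)
  if (use_adjusted) {
    yfit <- setNames(p$y_adjusted, ids)
    X <- matrix(1, length(ids), 1L)
  } else {
    yfit <- setNames(p$y_raw, ids)
    X <- build_fixed_design(p)
  }
  spec_full <- mixed_model_spec(yfit, X, G)
  vc_full <- fit_reml(spec_full)

  if (is.null(folds)) {
    families <- if (!is.null(p$sire)) setNames(p$sire, p$animal_id) else NULL
    folds <- make_folds(ids, cfg, families = families)
  }
  fold_hash <- fnv1a_hash(paste(names(folds), folds, collapse = ";"))

  h2_used <- if (is.numeric(h2)) h2 else if (identical(h2, "panel"))
    vc_full$h2 else NA_real_

  accs <- rep(NA_real_, cfg$n_folds)
  gebv_out <- setNames(rep(NA_real_, length(ids)), ids)
  for (f in seq_len(cfg$n_folds)) {
    mask <- ids[folds == f]
    train_ids <- setdiff(ids, mask)
    tr <- match(train_ids, ids)
    spec_f <- mixed_model_spec(yfit[tr], X[tr, , drop = FALSE], G)
    vc_f <- fit_reml(spec_f)
    if (!isTRUE(vc_f$converged) || !is.finite(vc_f$h2) ||
        vc_f$h2 <= min_h2_train) {
      warning("fold ", f, " skipped: unusable training heritability",
              call. = FALSE)
      next
    }
    gebv <- predict_gebv(spec_f, vc_f)
    gv <- gebv$gebv[match(mask, gebv$animal_id)]
    gebv_out[mask] <- gv
    h2f <- if (identical(h2, "per_fold")) vc_f$h2 else h2_used
    if (!is.finite(h2f)) h2f <- vc_f$h2
    accs[f] <- cor(gv, p$y_corrected[match(mask, p$animal_id)]) /
      sqrt(max(h2f, h2_floor))
  }
  ok <- is.finite(accs)
  if (sum(ok) < 2L) stop_("fewer than 2 usable folds")
  structure(list(panel_name = if (is.null(panel)) "ALL" else panel$name,
                 fold_accuracies = accs,
                 mean_accuracy = mean(accs[ok]),
                 sd_accuracy = sd(accs[ok]),
                 h2_used = if (is.numeric(h2)) h2 else
                   if (identical(h2, "panel")) h2_used else NA_real_,
                 fold_hash = fold_hash, n_folds = cfg$n_folds,
                 gebv = gebv_out, vc_full = vc_full),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result '%s': mean accuracy %.3f (%.3f) over %d folds, h2_used %.3f\n",
              x$panel_name, x$mean_accuracy, x$sd_accuracy,
              sum(is.finite(x$fold_accuracies)), x$h2_used))
  invisible(x)
}

#' Compare panels evaluated on the same folds
#'
#' Requires all results to share the fold assignment (checked by hash);
#' differences are then paired by fold.
#'
#' @param results list of [cv_accuracy()] results.
#' @return data.frame sorted by decreasing mean accuracy, with the paired
#'   per-fold difference to the best panel (`diff_to_best`, `sd_diff`);
#'   the full pairwise mean-difference matrix is in attribute
#'   `"paired_diffs"`.
#' @export
panel_comparison <- function(results) {
  stopifnot(length(results) >= 2L)
  hashes <- vapply(results, `[[`, numeric(1), "fold_hash")
  if (length(unique(hashes)) != 1L)
    stop_("results use different fold assignments; cannot pair")
  nm <- vapply(results, `[[`, character(1), "panel_name")
  acc <- do.call(cbind, lapply(results, `[[`, "fold_accuracies"))
  colnames(acc) <- nm
  means <- colMeans(acc, na.rm = TRUE)
  o <- order(-means)
  best <- acc[, o[1]]
  dd <- best - acc
  out <- data.frame(panel = nm[o],
                    mean_accuracy = means[o],
                    sd_accuracy = apply(acc, 2L, sd, na.rm = TRUE)[o],
                    diff_to_best = colMeans(dd, na.rm = TRUE)[o],
                    sd_diff = apply(dd, 2L, sd, na.rm = TRUE)[o],
                    row.names = NULL, stringsAsFactors = FALSE)
  pd <- outer(seq_along(nm), seq_along(nm), Vectorize(function(i, j)
    mean(acc[, i] - acc[, j], na.rm = TRUE)))
  dimnames(pd) <- list(nm, nm)
  attr(out, "paired_diffs") <- pd
  out
}
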