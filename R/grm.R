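#' VanRaden genomic relationship matrix
#'
#' Centers each SNP's dosage by twice its allele frequency
#' (`W_jk = x_jk - 2 p_k`, equivalently the AA/AB/BB codes
#' `2-2p`, `1-2p`, `-2p` with the counted allele as B) and scales the
#' cross-product by `2 * sum(p_k * (1 - p_k))`:
#' `G = W W' / (2 sum p q)`. Frequencies come from the analyzed cohort
#' itself unless `freq` is supplied (e.g. fixed from a reference cohort).
#'
#' @param g a complete [genotype_matrix()].
#' @param panel optional [snp_panel()] restricting the SNPs used; default
#'   all SNPs. Panel SNPs monomorphic in `g` are dropped with a warning.
#' @param freq optional named vector of counted-allele frequencies
#'   (overrides observed frequencies).
#' @param name label stored on the result (defaults to the panel name).
#' @return list of class `grm`: `matrix` (n x n symmetric), `animal_ids`,
#'   `m_snps`, `denominator`, `allele_freqs`, `ridge_used` (0 here; set by
#'   downstream consumers that stabilize an inversion), `name`.
#' @export
build_vanraden <- function(g, panel = NULL, freq = NULL, name = NULL) {
  check_complete(g)
  if (!is.null(panel)) {
    missing_ids <- setdiff(panel$snp_ids, g$map$snp_id)
    if (length(missing_ids))
      stop_("panel SNPs absent from genotypes: ",
            paste(head(missing_ids, 5L), collapse = ", "))
    cols <- match(panel$snp_ids, g$map$snp_id)
  } else {
    cols <- seq_len(n_snps(g))
  }
  d <- g$dosage[, cols, drop = FALSE]
  ids <- g$map$snp_id[cols]
  if (is.null(freq)) {
    p <- colMeans(d) / 2
  } else {
    p <- unname(freq[ids])
    if (anyNA(p)) stop_("freq vector lacks entries for some panel SNPs")
  }
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNP(s) dropped from GRM", call. = FALSE)
    d <- d[, poly, drop = FALSE]
    p <- p[poly]
    ids <- ids[poly]
  }
  den <- 2 * sum(p * (1 - p))
  if (!length(p) || den <= 0)
    stop_("GRM denominator is zero (no polymorphic SNPs)")
  W <- sweep(d, 2L, 2 * p, "-")
  G <- tcrossprod(W) / den
  structure(list(matrix = G, animal_ids = rownames(g$dosage),
                 m_snps = length(p), denominator = den,
                 allele_freqs = setNames(p, ids), ridge_used = 0,
                 name = name %||% (if (is.null(panel)) "ALL" else panel$name)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm '%s': %d animals, %d SNPs, denominator %.3f\n",
              x$name, length(x$animal_ids), x$m_snps, x$denominator))
  invisible(x)
}

#' GRM diagnostics: element distributions, inverse spread, multimodality
#'
#' Summarizes the diagonal and strict upper-triangle off-diagonal elements,
#' inverts the matrix (adding `ridge * I` only if the plain inversion
#' fails, and recording the ridge actually used), and screens the diagonal
#' for multimodality with Sarle's bimodality coefficient — multiple peaks
#' in GRM diagonals are a classic sign of hidden subpopulations or
#' mislabelled animals. Low-density panels inflate the spread of both the
#' GRM and its inverse; these statistics make that visible.
#'
#' @param G a [build_vanraden()] result.
#' @param ridge ridge added to the diagonal when plain inversion fails.
#' @return list of class `grm_diagnostics`: `diag_*`, `offdiag_*`,
#'   `inv_diag_*` (NA when inversion failed even with ridge),
#'   `ridge_used`, `inversion_ok`, `multimodality_flag`,
#'   `bimodality_coefficient`.
#' @export
grm_diagnostics <- function(G, ridge = 0.01) {
  stopifnot(inherits(G, "grm"))
  M <- G$matrix
  n <- nrow(M)
  dg <- diag(M)
  od <- M[upper.tri(M)]
  stats4 <- function(x) {
    if (!length(x)) return(c(mean = NA_real_, sd = NA_real_,
                             min = NA_real_, max = NA_real_))
    c(mean = mean(x), sd = sd(x), min = min(x), max = max(x))
  }
  inv_ok <- TRUE
  ridge_used <- 0
  Minv <- tryCatch(chol2inv(chol(M)), error = function(e) NULL)
  if (is.null(Minv) && ridge > 0) {
    ridge_used <- ridge
    Minv <- tryCatch(chol2inv(chol(M + diag(ridge, n))),
                     error = function(e) NULL)
  }
  if (is.null(Minv)) {
    inv_ok <- FALSE
    inv_stats <- stats4(numeric(0))
  } else {
    inv_stats <- stats4(diag(Minv))
  }
  bc <- bimodality_coefficient(dg)
  out <- c(as.list(setNames(stats4(dg), paste0("diag_", names(stats4(dg))))),
           as.list(setNames(stats4(od), paste0("offdiag_", names(stats4(od))))),
           as.list(setNames(inv_stats, paste0("inv_diag_", names(inv_stats)))))
  out$ridge_used <- ridge_used
  out$inversion_ok <- inv_ok
  out$bimodality_coefficient <- bc
  out$multimodality_flag <- is.finite(bc) && bc > 0.555
  class(out) <- "grm_diagnostics"
  out
}

# Sarle's bimodality coefficient: (skew^2 + 1) / (excess kurtosis +
# 3 (n-1)^2 / ((n-2)(n-3))). > 0.555 (the uniform's value) flags possible
# bimodality.
bimodality_coefficient <- function(x) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  xc <- x - mean(x)
  s2 <- mean(xc^2)
  if (s2 <= 0) return(NA_real_)
  g1 <- mean(xc^3) / s2^1.5
  g2 <- mean(xc^4) / s2^2 - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Write / read a GRM
#'
#' `write_grm()` emits the pairwise text dialect used by GCTA
#' (`<prefix>.grm.txt`: id1 index, id2 index, SNP count, value, lower
#' triangle including the diagonal; `<prefix>.grm.id`: family and within-
#' family id columns) plus a square-matrix TSV (`<prefix>.grm.tsv`).
#' `read_grm()` reads the pair back.
#'
#' @param G a `grm`.
#' @param prefix output path prefix.
#' @return `write_grm`: `prefix`, invisibly. `read_grm`: a `grm` (with
#'   `denominator`/`allele_freqs` unknown, set to `NA`).
#' @export
write_grm <- function(G, prefix) {
  stopifnot(inherits(G, "grm"))
  n <- length(G$animal_ids)
  idx <- which(lower.tri(G$matrix, diag = TRUE), arr.ind = TRUE)
  pairs <- data.frame(id1 = idx[, 1], id2 = idx[, 2], m = G$m_snps,
                      value = G$matrix[idx])
  o <- order(pairs$id1, pairs$id2)
  data.table::fwrite(pairs[o, ], paste0(prefix, ".grm.txt"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  data.table::fwrite(data.frame(fid = G$animal_ids, iid = G$animal_ids),
                     paste0(prefix, ".grm.id"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  sq <- data.frame(animal_id = G$animal_ids, G$matrix, check.names = FALSE)
  colnames(sq)[-1] <- G$animal_ids
  data.table::fwrite(sq, paste0(prefix, ".grm.tsv"), sep = "\t", quote = FALSE)
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  ids <- data.table::fread(paste0(prefix, ".grm.id"), header = FALSE,
                           data.table = FALSE)[[2]]
  pairs <- data.table::fread(paste0(prefix, ".grm.txt"), header = FALSE,
                             data.table = FALSE)
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  M[cbind(pairs[[1]], pairs[[2]])] <- pairs[[4]]
  M[cbind(pairs[[2]], pairs[[1]])] <- pairs[[4]]
  structure(list(matrix = M, animal_ids = as.character(ids),
                 m_snps = pairs[[3]][1], denominator = NA_real_,
                 allele_freqs = NULL, ridge_used = 0, name = basename(prefix)),
            class = "grm")
}
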