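#' Single-GRM mixed model specification
#'
#' The model `y = X b + Z a + e` with `a ~ N(0, sigma2_a * G)` and
#' `e ~ N(0, sigma2_e * I)`. Observations are matched to animals in `G` by
#' the names of `y`; `Z` is the implied incidence matrix (one record per
#' animal here, so `Z G Z'` is the observed-animal submatrix of `G`).
#'
#' @param y named numeric vector of phenotypes (names are animal ids
#'   present in `G`).
#' @param X fixed-effect design matrix for the rows of `y` (include the
#'   intercept column); reduced to full column rank internally.
#' @param G a [build_vanraden()] result (or any `grm`).
#' @return list of class `mixed_model_spec`.
#' @export
mixed_model_spec <- function(y, X, G) {
  stopifnot(inherits(G, "grm"))
  if (is.null(names(y))) stop_("y must be named by animal id")
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  stopifnot(nrow(X) == length(y))
  idx <- match(names(y), G$animal_ids)
  if (anyNA(idx)) stop_("phenotyped animal(s) missing from the GRM")
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  structure(list(y = y, X = X, G = G, obs_idx = idx),
            class = "mixed_model_spec")
}

#' Construct the intercept + contemporary group + age design matrix
#'
#' @param p a [phenotype_table()] (rows define the design rows).
#' @return model matrix with treatment contrasts on `group` and linear age.
#' @export
build_fixed_design <- function(p) {
  grp <- factor(p$group)
  dat <- data.frame(grp = grp, age = as.numeric(p$age_days))
  if (nlevels(grp) > 1L) model.matrix(~ grp + age, dat)
  else model.matrix(~ age, dat)
}

#' REML variance components for the single-GRM model
#'
#' Maximizes the restricted likelihood by the eigendecomposition route:
#' with `H = Z G Z' = U D U'`, rotating `y` and `X` by `U'` makes
#' `V = sigma2_e (I + lambda D)` diagonal in the rotated basis
#' (`lambda = sigma2_a / sigma2_e`), so the restricted likelihood can be
#' profiled over `lambda` by 1-D bounded search on the log scale, with the
#' variance scale recovered in closed form at the optimum. Standard errors
#' come from the inverse average-information matrix; `se_h2` by the delta
#' method.
#'
#' @param spec a [mixed_model_spec()].
#' @param ratio_bounds search bounds for `lambda`.
#' @param tol optimizer tolerance on the log-ratio scale.
#' @return list of class `variance_components`: `sigma2_a`, `sigma2_e`,
#'   `sigma2_p`, `h2`, `se_sigma2_a`, `se_sigma2_e`, `se_h2`,
#'   `loglik_reml`, `converged`, `boundary`, `flags`, `lambda`.
#' @export
fit_reml <- function(spec, ratio_bounds = c(1e-6, 1e6), tol = 1e-8) {
  stopifnot(inherits(spec, "mixed_model_spec"))
  y <- as.numeric(spec$y)
  X <- spec$X
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2L) stop_("need at least ncol(X) + 2 observations")
  H <- spec$G$matrix[spec$obs_idx, spec$obs_idx, drop = FALSE]
  eg <- eigen(H, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)

  if (diff(range(d)) <= 1e-8 * max(1, max(d))) {
    vc <- empty_vc()
    vc$flags <- "not_identifiable"
    vc$sigma2_p <- sum(lm.fit(X, y)$residuals^2) / (n - p)
    return(vc)
  }

  prof <- function(loglam) profile_reml(exp(loglam), d, yt, Xt, n, p)$ll
  opt <- optimize(prof, interval = log(ratio_bounds), maximum = TRUE,
                  tol = tol)
  lambda <- exp(opt$maximum)
  at_lo <- opt$maximum <= log(ratio_bounds[1]) + 1e-4
  at_hi <- opt$maximum >= log(ratio_bounds[2]) - 1e-4
  sol <- profile_reml(lambda, d, yt, Xt, n, p)
  sigma2_e <- sol$sigma2_e
  sigma2_a <- lambda * sigma2_e
  h2 <- sigma2_a / (sigma2_a + sigma2_e)

  se <- tryCatch(
    reml_ai_se(lambda, sigma2_a, sigma2_e, d, yt, Xt),
    error = function(e) list(se_a = NA_real_, se_e = NA_real_,
                             se_h2 = NA_real_))

  structure(list(sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 sigma2_p = sigma2_a + sigma2_e, h2 = h2,
                 se_sigma2_a = se$se_a, se_sigma2_e = se$se_e,
                 se_h2 = se$se_h2, loglik_reml = sol$ll,
                 converged = TRUE, boundary = at_lo || at_hi,
                 flags = if (at_lo) "sigma2_a_boundary"
                         else if (at_hi) "sigma2_e_boundary" else "",
                 lambda = lambda, n = n, p = p),
            class = "variance_components")
}

empty_vc <- function() {
  structure(list(sigma2_a = NA_real_, sigma2_e = NA_real_,
                 sigma2_p = NA_real_, h2 = NA_real_,
                 se_sigma2_a = NA_real_, se_sigma2_e = NA_real_,
                 se_h2 = NA_real_, loglik_reml = NA_real_,
                 converged = FALSE, boundary = FALSE, flags = "",
                 lambda = NA_real_, n = NA_integer_, p = NA_integer_),
            class = "variance_components")
}

# Profiled restricted log-likelihood at variance ratio lambda, in the
# rotated basis. Returns the full REML log-likelihood (with constants),
# the GLS solution and the profiled sigma2_e.
profile_reml <- function(lambda, d, yt, Xt, n, p) {
  v <- 1 + lambda * d
  w <- 1 / v
  A <- crossprod(Xt, Xt * w)
  beta <- solve(A, crossprod(Xt, yt * w))
  r <- yt - Xt %*% beta
  rss <- sum(w * r^2)
  sigma2_e <- rss / (n - p)
  ldA <- determinant(A, logarithm = TRUE)$modulus
  ll <- -0.5 * ((n - p) * log(2 * pi * sigma2_e) + (n - p) +
                  sum(log(v)) + ldA)
  list(ll = as.numeric(ll), beta = beta, sigma2_e = sigma2_e, w = w)
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the (unprofiled) REML log-likelihood
#' `-(1/2) [ (n-p) log 2 pi + log|V| + log|X' V^-1 X| + y' P y ]`
#' through the eigen-path parameterization. Exposed so an independent
#' direct-matrix computation can be checked against it.
#'
#' @param spec a [mixed_model_spec()].
#' @param sigma2_a,sigma2_e variance components (`sigma2_e > 0`).
#' @return log restricted likelihood (numeric scalar).
#' @export
reml_loglik <- function(spec, sigma2_a, sigma2_e) {
  stopifnot(inherits(spec, "mixed_model_spec"), sigma2_e > 0, sigma2_a >= 0)
  y <- as.numeric(spec$y)
  X <- spec$X
  n <- length(y)
  p <- ncol(X)
  H <- spec$G$matrix[spec$obs_idx, spec$obs_idx, drop = FALSE]
  eg <- eigen(H, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)
  lambda <- sigma2_a / sigma2_e
  v <- 1 + lambda * d
  w <- 1 / v
  A <- crossprod(Xt, Xt * w)
  beta <- solve(A, crossprod(Xt, yt * w))
  r <- yt - Xt %*% beta
  yPy <- sum(w * r^2) / sigma2_e
  logdetV <- n * log(sigma2_e) + sum(log(v))
  logdetXVX <- as.numeric(determinant(A, logarithm = TRUE)$modulus) -
    p * log(sigma2_e)
  -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetXVX + yPy)
}

# Average-information standard errors at the optimum, in the rotated basis.
reml_ai_se <- function(lambda, sigma2_a, sigma2_e, d, yt, Xt) {
  v <- sigma2_e * (1 + lambda * d) # rotated V diagonal
  Xw <- Xt / v
  A <- crossprod(Xt, Xw)
  Ainv <- solve(A)
  applyP <- function(z) {
    zv <- z / v
    zv - Xw %*% (Ainv %*% crossprod(Xt, zv))
  }
  Py <- applyP(yt)
  ta <- d * Py       # (dV/dsigma2_a) Py = D Py in rotated basis
  te <- Py           # dV/dsigma2_e = I
  Pta <- applyP(ta)
  Pte <- applyP(te)
  AI <- matrix(c(sum(ta * Pta), sum(ta * Pte),
                 sum(ta * Pte), sum(te * Pte)) / 2, 2L, 2L)
  Vc <- solve(AI)
  sp2 <- (sigma2_a + sigma2_e)^2
  grad <- c(sigma2_e, -sigma2_a) / sp2
  list(se_a = sqrt(max(Vc[1, 1], 0)), se_e = sqrt(max(Vc[2, 2], 0)),
       se_h2 = sqrt(max(t(grad) %*% Vc %*% grad, 0)))
}

#' @export
print.variance_components <- function(x, ...) {
  fmt <- function(v, s) sprintf("%.3f (%.3f)", v, s)
  cat("REML variance components (genomic):\n")
  cat("  sigma2_a:", fmt(x$sigma2_a, x$se_sigma2_a), "\n")
  cat("  sigma2_e:", fmt(x$sigma2_e, x$se_sigma2_e), "\n")
  cat("  sigma2_p:", sprintf("%.3f", x$sigma2_p), "\n")
  cat("  h2      :", fmt(x$h2, x$se_h2), "\n")
  cat(sprintf("  logLik %.4f, converged %s%s\n", x$loglik_reml, x$converged,
              if (nzchar(x$flags)) paste0(" [", x$flags, "]") else ""))
  invisible(x)
}

#' Genomic breeding values (GBLUP), including unphenotyped animals
#'
#' Solves the mixed-model equations on the observed records only and
#' back-solves breeding values for every animal in the GRM:
#' `a_hat = sigma2_a * G[, obs] V_obs^-1 (y - X b_hat)` with
#' `V_obs = sigma2_a * H + sigma2_e * I`. Animals listed in `unphenotyped`
#' are masked from the fit but still receive a GEBV.
#'
#' @param spec a [mixed_model_spec()].
#' @param vc fitted [fit_reml()] result.
#' @param unphenotyped character ids to mask (subset of the spec's
#'   phenotyped animals); animals in `G` with no phenotype at all are
#'   predicted automatically.
#' @param reliability also compute per-animal reliability
#'   `1 - PEV / (sigma2_a G_ii)`.
#' @return data.frame of class `gebv_table`: `animal_id`, `gebv`
#'   (one row per animal in `G`), optionally `reliability`.
#' @export
predict_gebv <- function(spec, vc, unphenotyped = character(),
                         reliability = FALSE) {
  stopifnot(inherits(spec, "mixed_model_spec"),
            inherits(vc, "variance_components"))
  if (!isTRUE(vc$converged)) stop_("variance components did not converge")
  keep <- !(names(spec$y) %in% unphenotyped)
  if (!any(keep)) stop_("all animals unphenotyped; nothing to fit on")
  y <- as.numeric(spec$y[keep])
  X <- spec$X[keep, , drop = FALSE]
  obs <- spec$obs_idx[keep]
  G <- spec$G$matrix
  H <- G[obs, obs, drop = FALSE]
  no <- length(y)
  V <- vc$sigma2_a * H + diag(vc$sigma2_e, no)
  Vi <- chol2inv(chol(V))
  XtVi <- crossprod(X, Vi)
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  a <- as.numeric(vc$sigma2_a * G[, obs, drop = FALSE] %*% (Vi %*% r))
  out <- data.frame(animal_id = spec$G$animal_ids, gebv = a,
                    stringsAsFactors = FALSE)
  if (reliability) {
    # P = Vi - Vi X (X' Vi X)^-1 X' Vi  on observed records
    B <- solve(XtVi %*% X, XtVi)
    Pm <- Vi - t(XtVi) %*% B
    Cg <- G[, obs, drop = FALSE]
    quad <- rowSums((Cg %*% Pm) * Cg)
    denom <- diag(G)
    rel <- ifelse(denom > 0, vc$sigma2_a * quad / denom, NA_real_)
    out$reliability <- pmin(pmax(rel, 0), 1)
  }
  attr(out, "beta") <- beta
  class(out) <- c("gebv_table", "data.frame")
  out
}

#' Share of the all-SNP additive variance captured by a subset panel
#'
#' @param vc_subset,vc_all [fit_reml()] results on the same cohort.
#' @return percentage `100 * sigma2_a(subset) / sigma2_a(all)`.
#' @export
variance_share <- function(vc_subset, vc_all) {
  if (!is.finite(vc_all$sigma2_a) || vc_all$sigma2_a <= 0)
    stop_("all-SNP additive variance is zero; share undefined")
  100 * vc_subset$sigma2_a / vc_all$sigma2_a
}
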