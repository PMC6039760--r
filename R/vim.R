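#' Random forest parameters
#'
#' Defaults follow common regression-forest practice: `sample_fraction`
#' 2/3 drawn without replacement (a bootstrap flag is available),
#' `min_node_size` 5, unlimited depth, and `mtry = sqrt(m)` unless an
#' explicit `mtry` or `mtry_frac` (e.g. 0.1 for 10% of SNPs, the tuned
#' choice for dense panels) is given.
#'
#' @param ntree number of trees.
#' @param mtry candidate SNPs per split; overrides `mtry_frac`.
#' @param mtry_frac fraction of SNPs as candidates per split.
#' @param sample_fraction fraction of animals per tree.
#' @param bootstrap sample with replacement (classical bootstrap) instead
#'   of the default without-replacement subsample.
#' @param min_node_size node becomes a leaf at or below this size.
#' @param max_depth maximum tree depth; 0 = unlimited.
#' @param seed RNG seed.
#' @return list of class `rf_params`.
#' @export
rf_params <- function(ntree = 500L, mtry = NULL, mtry_frac = NULL,
                      sample_fraction = 2 / 3, bootstrap = FALSE,
                      min_node_size = 5L, max_depth = 0L, seed = 1L) {
  stopifnot(ntree >= 1L, sample_fraction > 0, sample_fraction <= 1)
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 mtry_frac = mtry_frac, sample_fraction = sample_fraction,
                 bootstrap = isTRUE(bootstrap),
                 min_node_size = as.integer(min_node_size),
                 max_depth = as.integer(max_depth), seed = as.integer(seed)),
            class = "rf_params")
}

#' Boosting parameters (shared by the first- and second-order boosters)
#'
#' `reg_lambda` (ridge on leaf weights) and `reg_gamma` (per-split penalty)
#' apply to the second-order method only. Defaults where tuning is silent:
#' depth 3, `min_samples_leaf` 10, `subsample` 1, `lambda` 1, `gamma` 0.
#'
#' @param ntree number of boosting stages.
#' @param learning_rate shrinkage in `(0, 1]`.
#' @param max_depth maximum tree depth (>= 1).
#' @param min_samples_leaf minimum rows per leaf.
#' @param subsample per-stage row subsampling fraction.
#' @param reg_lambda ridge penalty on leaf weights (second-order only).
#' @param reg_gamma minimum-gain penalty per split (second-order only).
#' @param seed RNG seed.
#' @return list of class `boost_params`.
#' @export
boost_params <- function(ntree = 500L, learning_rate = 0.1, max_depth = 3L,
                         min_samples_leaf = 10L, subsample = 1.0,
                         reg_lambda = 1.0, reg_gamma = 0.0, seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate <= 0 || learning_rate > 1)
    stop_("learning_rate must lie in (0, 1]")
  if (reg_lambda < 0) stop_("reg_lambda must be >= 0")
  if (reg_gamma < 0) stop_("reg_gamma must be >= 0")
  stopifnot(ntree >= 1L, max_depth >= 1L)
  structure(list(ntree = as.integer(ntree), learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 subsample = subsample, reg_lambda = reg_lambda,
                 reg_gamma = reg_gamma, seed = as.integer(seed)),
            class = "boost_params")
}

#' Variable importance table
#'
#' One row per SNP with the importance `score` and its `rank` (1 = most
#' important). Ranks are a permutation of `1..m`; ties in score are broken
#' by genome order (the SNP map's chromosome/position order), so ranking is
#' deterministic.
#'
#' @param method one of `"rf_permutation"`, `"gbm_influence"`, `"xgb_gain"`.
#' @param map SNP map (genome-ordered).
#' @param score numeric importance per SNP, in map order.
#' @return data.frame of class `vim_table` with columns `snp_id`, `chrom`,
#'   `pos_bp`, `score`, `rank`.
#' @export
vim_table <- function(method, map, score) {
  stopifnot(length(score) == nrow(map))
  ord <- order(-score, seq_along(score))
  rnk <- integer(length(score))
  rnk[ord] <- seq_along(score)
  out <- data.frame(snp_id = map$snp_id, chrom = map$chrom,
                    pos_bp = map$pos_bp, score = score, rank = rnk,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("vim_table", "data.frame")
  out
}

check_complete <- function(g) {
  if (anyNA(g$dosage))
    stop_("genotypes contain missing calls; run qc_filter() first")
}

resolve_mtry <- function(params, m) {
  if (!is.null(params$mtry)) return(max(1L, min(as.integer(params$mtry), m)))
  if (!is.null(params$mtry_frac))
    return(max(1L, min(as.integer(ceiling(params$mtry_frac * m)), m)))
  max(1L, as.integer(floor(sqrt(m))))
}

#' Random forest permutation importance (%IncMSE)
#'
#' Per tree: subsample animals, grow a CART regression tree with `mtry`
#' candidate SNPs per split, compute the out-of-bag (OOB) MSE; then for each
#' SNP used in the tree, permute its OOB column and recompute the MSE. A
#' SNP's score is the mean over the trees containing it of
#' `(MSE_permuted - MSE_oob) / MSE_oob * 100`; SNPs never used score 0 and
#' negative scores are preserved. One OOB permutation is drawn per tree and
#' applied to each used SNP in turn (see the methods vignette).
#'
#' @param g a complete (QC'd) [genotype_matrix()].
#' @param y_adjusted numeric adjusted phenotype, one per animal in `g`.
#' @param params an [rf_params()].
#' @return a [vim_table()] (method `"rf_permutation"`); attributes:
#'   `trees_used` (per-SNP tree counts, the OOB coverage flag),
#'   `oob_mse` (per-tree OOB MSE), `forest_oob_mse` (MSE of the
#'   forest-aggregated OOB predictions — the tuning-curve statistic).
#' @export
rf_importance <- function(g, y_adjusted, params = rf_params()) {
  check_complete(g)
  n <- n_animals(g); m <- n_snps(g)
  stopifnot(length(y_adjusted) == n)
  set.seed(params$seed)
  k <- max(1L, round(params$sample_fraction * n))
  subsamples <- vector("list", params$ntree)
  perms <- vector("list", params$ntree)
  for (t in seq_len(params$ntree)) {
    s <- sample.int(n, k, replace = params$bootstrap)
    subsamples[[t]] <- s
    n_oob <- n - length(unique(s))
    perms[[t]] <- if (n_oob > 0L) sample.int(n_oob) else integer(0)
  }
  res <- rf_forest_cpp(g$dosage, as.numeric(y_adjusted), subsamples, perms,
                       resolve_mtry(params, m), params$min_node_size,
                       params$max_depth)
  out <- vim_table("rf_permutation", g$map, res$score)
  attr(out, "trees_used") <- res$trees_used
  attr(out, "oob_mse") <- res$oob_mse
  covered <- res$oob_pred_cnt > 0L
  attr(out, "forest_oob_mse") <- if (any(covered))
    mean((y_adjusted[covered] -
            res$oob_pred_sum[covered] / res$oob_pred_cnt[covered])^2)
  else NA_real_
  attr(out, "params") <- params
  out
}

#' Gradient boosting relative influence
#'
#' Least-squares gradient boosting: the fit starts at the phenotype mean
#' and at each stage adds `learning_rate` times a depth-limited CART tree
#' fitted to the current residuals. A SNP's relative influence is the sum,
#' over all splits on that SNP in all stages, of the split's squared-error
#' improvement; scores are therefore non-negative.
#'
#' @inheritParams rf_importance
#' @param params a [boost_params()].
#' @return a [vim_table()] (method `"gbm_influence"`).
#' @export
gbm_importance <- function(g, y_adjusted, params = boost_params()) {
  check_complete(g)
  n <- n_animals(g)
  stopifnot(length(y_adjusted) == n)
  set.seed(params$seed)
  res <- gbm_cpp(g$dosage, as.numeric(y_adjusted), seq_len(n),
                 params$ntree, params$learning_rate, params$max_depth,
                 params$min_samples_leaf, params$subsample, integer(0))
  out <- vim_table("gbm_influence", g$map, res$influence)
  attr(out, "fitted") <- res$fitted
  attr(out, "train_mse") <- res$train_mse
  attr(out, "params") <- params
  out
}

#' Second-order boosting gain importance
#'
#' Boosting with squared loss expanded to second order: with gradient
#' `g_i = f(x_i) - y_i` and unit hessians, a split's gain is
#' `0.5 * (G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) - (G_L+G_R)^2/(H_L+H_R+lambda)) - gamma`
#' and a leaf's weight is `-G/(H+lambda)`. A SNP's score is its total gain
#' over all splits, normalized to sum to 1 across SNPs.
#'
#' @inheritParams gbm_importance
#' @return a [vim_table()] (method `"xgb_gain"`).
#' @export
xgb_importance <- function(g, y_adjusted, params = boost_params()) {
  check_complete(g)
  n <- n_animals(g)
  stopifnot(length(y_adjusted) == n)
  set.seed(params$seed)
  res <- xgb_cpp(g$dosage, as.numeric(y_adjusted), seq_len(n),
                 params$ntree, params$learning_rate, params$max_depth,
                 params$min_samples_leaf, params$subsample,
                 params$reg_lambda, params$reg_gamma, integer(0))
  total <- sum(res$gain)
  score <- if (total > 0) res$gain / total else res$gain
  out <- vim_table("xgb_gain", g$map, score)
  attr(out, "gain_raw") <- res$gain
  attr(out, "fitted") <- res$fitted
  attr(out, "params") <- params
  out
}

#' Second-order split gain
#'
#' The regularized gain of splitting a node with gradient/hessian sums
#' `(G_L, H_L)` and `(G_R, H_R)`:
#' `0.5 * (G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) - (G_L+G_R)^2/(H_L+H_R+lambda)) - gamma`.
#' This is the criterion the second-order booster maximizes at every node.
#'
#' @param G_L,H_L,G_R,H_R gradient and hessian sums of the two children.
#' @param lambda ridge penalty on leaf weights.
#' @param gamma per-split penalty.
#' @return numeric gain.
#' @export
xgb_split_gain <- function(G_L, H_L, G_R, H_R, lambda = 1, gamma = 0) {
  0.5 * (G_L^2 / (H_L + lambda) + G_R^2 / (H_R + lambda) -
           (G_L + G_R)^2 / (H_L + H_R + lambda)) - gamma
}

#' Fit a single CART regression tree on dosage data
#'
#' Greedy CART restricted to the two admissible thresholds (0.5, 1.5) on
#' 0/1/2 dosages: at each node the candidate SNP and threshold maximizing
#' the sum-of-squared-error reduction is chosen; leaves predict the node
#' mean. Split improvements are recorded on internal nodes. A constant
#' response yields a single-leaf tree.
#'
#' @param X dosage matrix or [genotype_matrix()].
#' @param y numeric response.
#' @param candidate_snps column indices eligible for splitting (default all).
#' @param min_node_size leaf size bound.
#' @param max_depth maximum depth, 0 = unlimited.
#' @param rows row indices to train on (default all).
#' @return list of class `dosage_tree` with parallel node arrays (`var` is
#'   0-based, -1 for leaves), per-node split `gain`, and `pred`, the
#'   predictions for all rows of `X`.
#' @export
fit_regression_tree <- function(X, y, candidate_snps = NULL,
                                min_node_size = 5L, max_depth = 0L,
                                rows = NULL) {
  if (inherits(X, "genotype_matrix")) X <- X$dosage
  storage.mode(X) <- "integer"
  if (anyNA(X)) stop_("dosage matrix must be complete (no missing calls)")
  stopifnot(length(y) == nrow(X))
  if (is.null(candidate_snps)) candidate_snps <- seq_len(ncol(X))
  if (is.null(rows)) rows <- seq_len(nrow(X))
  out <- tree_cpp(X, as.numeric(y), as.integer(rows),
                  as.integer(candidate_snps), as.integer(min_node_size),
                  as.integer(max_depth))
  class(out) <- "dosage_tree"
  out
}

#' Parameter tuning curve with plateau detection
#'
#' For each grid row, fits the requested ranker and records a held-out MSE:
#' the forest-aggregated OOB MSE for `"rf"`, or a seeded 20% validation-fold MSE
#' at the final stage for `"gbm"`/`"xgb"`. The plateau is the smallest grid
#' index whose MSE is within `rel_tol` of the grid minimum — the "no longer
#' changing" point used to pick minimal safe settings.
#'
#' @param g a complete [genotype_matrix()].
#' @param y_adjusted numeric adjusted phenotype.
#' @param method `"rf"`, `"gbm"`, or `"xgb"`.
#' @param grid data.frame of parameter settings, one row per grid point
#'   (columns are [rf_params()]/[boost_params()] argument names). Rows
#'   should be ordered by increasing cost for the plateau to be meaningful.
#' @param seed seed for the validation split and fits.
#' @param rel_tol relative tolerance for the plateau detector.
#' @return list of class `tuning_curve`: `method`, `grid` (with a
#'   `mean_mse` column), `plateau` (row index).
#' @export
tuning_curve <- function(g, y_adjusted, method = c("rf", "gbm", "xgb"),
                         grid, seed = 1L, rel_tol = 0.02) {
  method <- match.arg(method)
  if (is.null(dim(grid)) || nrow(grid) == 0L) stop_("grid must be non-empty")
  if (anyDuplicated(grid)) stop_("grid points must be unique")
  n <- n_animals(g)
  set.seed(derive_seed(seed, "tuning_valid"))
  valid <- sort(sample.int(n, max(2L, round(n / 5))))
  train <- setdiff(seq_len(n), valid)
  mse <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    args <- as.list(grid[i, , drop = FALSE])
    args$seed <- derive_seed(seed, paste0("tuning_fit_", i))
    if (method == "rf") {
      v <- rf_importance(g, y_adjusted, do.call(rf_params, args))
      mse[i] <- attr(v, "forest_oob_mse")
    } else {
      pr <- do.call(boost_params, args)
      set.seed(pr$seed)
      fn <- if (method == "gbm") {
        function() gbm_cpp(g$dosage, as.numeric(y_adjusted), train, pr$ntree,
                           pr$learning_rate, pr$max_depth,
                           pr$min_samples_leaf, pr$subsample, valid)
      } else {
        function() xgb_cpp(g$dosage, as.numeric(y_adjusted), train, pr$ntree,
                           pr$learning_rate, pr$max_depth,
                           pr$min_samples_leaf, pr$subsample,
                           pr$reg_lambda, pr$reg_gamma, valid)
      }
      res <- fn()
      mse[i] <- res$valid_mse[pr$ntree]
    }
  }
  grid$mean_mse <- mse
  structure(list(method = method, grid = grid,
                 plateau = find_plateau(mse, rel_tol)),
            class = "tuning_curve")
}

#' @rdname tuning_curve
#' @param mse numeric vector of MSE values along an ordered grid.
#' @return `find_plateau`: the smallest index whose MSE is within
#'   `rel_tol` (relative) of the minimum.
#' @export
find_plateau <- function(mse, rel_tol = 0.02) {
  stopifnot(length(mse) >= 1L)
  which(mse <= min(mse) * (1 + rel_tol))[1L]
}
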