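# Independent pure-R oracles: straight-line reimplementations used to
# check the compiled tree ensembles and the eigen-path REML. These stay
# deliberately naive (exhaustive enumeration, dense solves).

# Exhaustive best split over (snp, threshold in {0.5, 1.5}); same
# tie-breaking as the implementation (strictly greater improvement wins,
# candidates scanned in index order, threshold 0.5 before 1.5).
oracle_best_split <- function(X, y, rows, candidates = seq_len(ncol(X)),
                              min_leaf = 1) {
  n <- length(rows)
  S <- sum(y[rows])
  parent <- S^2 / n
  best <- list(imp = 0, var = NA_integer_, thr = NA_real_)
  for (v in candidates) {
    for (thr in c(0.5, 1.5)) {
      l <- rows[X[rows, v] <= thr]
      r <- rows[X[rows, v] > thr]
      if (length(l) < min_leaf || length(r) < min_leaf) next
      imp <- sum(y[l])^2 / length(l) + sum(y[r])^2 / length(r) - parent
      if (imp > best$imp) best <- list(imp = imp, var = v, thr = thr)
    }
  }
  best
}

# Recursive CART with the same stopping rules as the compiled grower.
oracle_tree <- function(X, y, rows, min_node = 5, max_depth = 0,
                        min_leaf = 1) {
  imp <- numeric(ncol(X))
  grow <- function(rows, depth) {
    n <- length(rows)
    can_split <- n > min_node && n >= 2 &&
      (max_depth <= 0 || depth < max_depth)
    bs <- if (can_split)
      oracle_best_split(X, y, rows, min_leaf = min_leaf)
    else list(imp = 0, var = NA_integer_)
    if (!can_split || is.na(bs$var) || bs$imp <= 0)
      return(list(leaf = TRUE, value = sum(y[rows]) / n))
    imp[bs$var] <<- imp[bs$var] + bs$imp
    l <- rows[X[rows, bs$var] <= bs$thr]
    r <- rows[X[rows, bs$var] > bs$thr]
    list(leaf = FALSE, var = bs$var, thr = bs$thr,
         left = grow(l, depth + 1), right = grow(r, depth + 1))
  }
  root <- grow(rows, 0)
  pred1 <- function(node, x, perm_var = NA, perm_val = NA) {
    while (!node$leaf) {
      xv <- if (!is.na(perm_var) && node$var == perm_var) perm_val
            else x[node$var]
      node <- if (xv <= node$thr) node$left else node$right
    }
    node$value
  }
  list(root = root, importance = imp, used = which(imp > 0),
       predict = function(Xn, perm_var = NA, perm_vals = NA)
         vapply(seq_len(nrow(Xn)), function(i)
           pred1(root, Xn[i, ],
                 perm_var,
                 if (!is.na(perm_var)) perm_vals[i] else NA), numeric(1)))
}

# Straight-line random forest permutation importance: replicates the
# package's RNG draw order exactly, so with mtry = m (no column sampling in
# the compiled grower) the scores must match bit for bit.
oracle_rf <- function(X, y, ntree, sample_fraction = 2 / 3, min_node = 5,
                      seed = 1) {
  n <- nrow(X); m <- ncol(X)
  set.seed(seed)
  k <- max(1L, round(sample_fraction * n))
  relimp <- numeric(m); cnt <- integer(m)
  draws <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    s <- sample.int(n, k)
    perm <- sample.int(n - length(unique(s)))
    draws[[t]] <- list(s = s, perm = perm)
  }
  for (t in seq_len(ntree)) {
    s <- draws[[t]]$s; perm <- draws[[t]]$perm
    oob <- setdiff(seq_len(n), s)
    tr <- oracle_tree(X, y, s, min_node = min_node)
    pred <- tr$predict(X[oob, , drop = FALSE])
    mse0 <- mean((y[oob] - pred)^2)
    if (mse0 <= 0 || !length(oob)) next
    for (v in tr$used) {
      pv <- X[oob[perm], v]
      predp <- tr$predict(X[oob, , drop = FALSE], perm_var = v,
                          perm_vals = pv)
      msep <- mean((y[oob] - predp)^2)
      relimp[v] <- relimp[v] + (msep - mse0) / mse0
      cnt[v] <- cnt[v] + 1L
    }
  }
  score <- numeric(m)
  score[cnt > 0] <- 100 * relimp[cnt > 0] / cnt[cnt > 0]
  list(score = score, cnt = cnt)
}

# Stage-wise least-squares boosting oracle (subsample = 1, deterministic).
oracle_gbm <- function(X, y, ntree, lr, max_depth, min_leaf = 1) {
  n <- nrow(X); m <- ncol(X)
  f <- rep(mean(y), n)
  influence <- numeric(m)
  for (t in seq_len(ntree)) {
    r <- y - f
    tr <- oracle_tree(X, r, seq_len(n), min_node = 2 * min_leaf - 1,
                      max_depth = max_depth, min_leaf = min_leaf)
    influence <- influence + tr$importance
    f <- f + lr * tr$predict(X)
  }
  list(influence = influence, fitted = f)
}

# Direct (solve-based) restricted log-likelihood; same convention as the
# package's eigen-path value:
# -(1/2) [(n-p) log 2pi + log|V| + log|X'V^-1X| + y'Py].
reml_ll_direct <- function(y, X, H, sigma2_a, sigma2_e) {
  n <- length(y); p <- ncol(X)
  V <- sigma2_a * H + sigma2_e * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       t(r) %*% Vi %*% r))
}
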