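// Tree-ensemble core for SNP variable importance on 0/1/2 dosage matrices.
//
// Dosage predictors admit only two split thresholds (0.5 and 1.5), so every
// split search is a single counting pass per candidate SNP over the node rows.
// All randomness is drawn from R's RNG (unif_rand) so results are fully
// reproducible under set.seed(); row subsamples and OOB permutations for the
// random forest are drawn in R and passed in, which lets a pure-R oracle
// reproduce the forest exactly when mtry == m (no column sampling).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> var;      // split SNP (0-based), -1 for a leaf
  std::vector<double> thr;   // 0.5 or 1.5
  std::vector<int> left, right;
  std::vector<double> value; // leaf prediction (node mean, or -G/(H+lambda))
  std::vector<double> gain;  // split improvement recorded on internal nodes

  int add_node() {
    var.push_back(-1); thr.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    value.push_back(0.0); gain.push_back(0.0);
    return (int)var.size() - 1;
  }
};

// mode 0: CART variance reduction, leaf value = node mean.
// mode 1: second-order boosting; y holds gradients (h_i = 1 for squared
//         loss), split gain = .5*(GL^2/(HL+l) + GR^2/(HR+l) - G^2/(H+l)) - g,
//         leaf value = -G/(H + lambda).
struct GrowCfg {
  int mode;
  int mtry;            // candidates drawn per split; == cand.size() -> all, in order
  int min_node;        // node becomes a leaf when n <= min_node
  int max_depth;       // 0 = unlimited
  int min_leaf;        // both children must keep >= min_leaf rows
  double lambda, gamma;
};

class Grower {
public:
  Grower(const IntegerMatrix& X, const std::vector<double>& y,
         const std::vector<int>& cand, const GrowCfg& cfg,
         std::vector<double>* influence, std::vector<char>* used)
    : X_(X), y_(y), cfg_(cfg), influence_(influence), used_(used) {
    cols_ = cand;
  }

  TreeNodes tree;

  int grow(std::vector<int>& rows, int depth) {
    int id = tree.add_node();
    const int n = (int)rows.size();
    double S = 0.0;
    for (int r : rows) S += y_[r];

    bool try_split = n > cfg_.min_node && n >= 2 &&
      (cfg_.max_depth <= 0 || depth < cfg_.max_depth);

    int best_var = -1; double best_thr = 0.0, best_imp = 0.0;
    if (try_split) best_split(rows, S, n, best_var, best_thr, best_imp);

    if (best_var < 0 || best_imp <= 0.0) {
      tree.value[id] = (cfg_.mode == 0) ? S / n : -S / (n + cfg_.lambda);
      return id;
    }

    tree.var[id] = best_var;
    tree.thr[id] = best_thr;
    tree.gain[id] = best_imp;
    if (influence_) (*influence_)[best_var] += best_imp;
    if (used_) (*used_)[best_var] = 1;

    std::vector<int> rl, rr;
    rl.reserve(n); rr.reserve(n);
    for (int r : rows) {
      if (X_(r, best_var) <= best_thr) rl.push_back(r); else rr.push_back(r);
    }
    rows.clear(); rows.shrink_to_fit();
    int li = grow(rl, depth + 1);
    int ri = grow(rr, depth + 1);
    tree.left[id] = li;
    tree.right[id] = ri;
    return id;
  }

private:
  const IntegerMatrix& X_;
  const std::vector<double>& y_;
  GrowCfg cfg_;
  std::vector<int> cols_;
  std::vector<double>* influence_;
  std::vector<char>* used_;

  void best_split(const std::vector<int>& rows, double S, int n,
                  int& best_var, double& best_thr, double& best_imp) {
    const int ncand = (int)cols_.size();
    const int mtry = std::min(cfg_.mtry, ncand);
    const bool sample_cols = mtry < ncand;
    const double H = (double)n;
    double parent = (cfg_.mode == 0)
      ? S * S / n
      : 0.5 * S * S / (H + cfg_.lambda);

    best_imp = 0.0; best_var = -1;
    for (int j = 0; j < mtry; ++j) {
      int v;
      if (sample_cols) {
        int k = j + (int)(unif_rand() * (ncand - j));
        if (k >= ncand) k = ncand - 1;
        std::swap(cols_[j], cols_[k]);
        v = cols_[j];
      } else {
        v = cols_[j];
      }
      int c[3] = {0, 0, 0};
      double s[3] = {0.0, 0.0, 0.0};
      for (int r : rows) {
        int gcall = X_(r, v);
        c[gcall]++; s[gcall] += y_[r];
      }
      for (int t = 0; t < 2; ++t) { // thresholds 0.5 (t=0) and 1.5 (t=1)
        int nL = (t == 0) ? c[0] : c[0] + c[1];
        double sL = (t == 0) ? s[0] : s[0] + s[1];
        int nR = n - nL;
        if (nL < cfg_.min_leaf || nR < cfg_.min_leaf) continue;
        double sR = S - sL;
        double imp;
        if (cfg_.mode == 0) {
          imp = sL * sL / nL + sR * sR / nR - parent;
        } else {
          imp = 0.5 * (sL * sL / (nL + cfg_.lambda) +
                       sR * sR / (nR + cfg_.lambda)) - parent - cfg_.gamma;
        }
        if (imp > best_imp) {
          best_imp = imp; best_var = v; best_thr = (t == 0) ? 0.5 : 1.5;
        }
      }
    }
  }
};

double predict_row(const TreeNodes& T, const IntegerMatrix& X, int r,
                   int perm_var = -1, double perm_val = 0.0) {
  int id = 0;
  while (T.var[id] >= 0) {
    double x = (T.var[id] == perm_var) ? perm_val : (double)X(r, T.var[id]);
    id = (x <= T.thr[id]) ? T.left[id] : T.right[id];
  }
  return T.value[id];
}

List tree_to_list(const TreeNodes& T) {
  return List::create(
    _["var"] = IntegerVector(T.var.begin(), T.var.end()),
    _["thr"] = NumericVector(T.thr.begin(), T.thr.end()),
    _["left"] = IntegerVector(T.left.begin(), T.left.end()),
    _["right"] = IntegerVector(T.right.begin(), T.right.end()),
    _["value"] = NumericVector(T.value.begin(), T.value.end()),
    _["gain"] = NumericVector(T.gain.begin(), T.gain.end()));
}

std::vector<int> all_cols(int m) {
  std::vector<int> v(m);
  for (int j = 0; j < m; ++j) v[j] = j;
  return v;
}

// Partial Fisher-Yates subsample of k elements from pool (in place prefix).
std::vector<int> sample_rows(std::vector<int> pool, int k) {
  int n = (int)pool.size();
  for (int j = 0; j < k; ++j) {
    int i = j + (int)(unif_rand() * (n - j));
    if (i >= n) i = n - 1;
    std::swap(pool[j], pool[i]);
  }
  pool.resize(k);
  return pool;
}

} // namespace

// Single CART regression tree on dosage data; rows/candidates are 1-based.
// [[Rcpp::export]]
List tree_cpp(IntegerMatrix X, NumericVector y, IntegerVector rows,
              IntegerVector candidates, int min_node, int max_depth) {
  std::vector<double> yy(y.begin(), y.end());
  std::vector<int> rr(rows.size());
  for (int i = 0; i < rows.size(); ++i) rr[i] = rows[i] - 1;
  std::vector<int> cand(candidates.size());
  for (int i = 0; i < candidates.size(); ++i) cand[i] = candidates[i] - 1;

  GrowCfg cfg{0, (int)cand.size(), min_node, max_depth, 1, 0.0, 0.0};
  Grower g(X, yy, cand, cfg, nullptr, nullptr);
  g.grow(rr, 0);

  NumericVector pred(X.nrow());
  for (int r = 0; r < X.nrow(); ++r) pred[r] = predict_row(g.tree, X, r);
  List out = tree_to_list(g.tree);
  out["pred"] = pred;
  return out;
}

// Random forest with OOB permutation importance (%IncMSE).
// subsamples/perms: per-tree in-bag rows (1-based) and a permutation of
// 1..n_oob applied to every used SNP's OOB column in turn.
// [[Rcpp::export]]
List rf_forest_cpp(IntegerMatrix X, NumericVector y, List subsamples,
                   List perms, int mtry, int min_node, int max_depth) {
  const int n = X.nrow(), m = X.ncol(), ntree = subsamples.size();
  std::vector<double> yy(y.begin(), y.end());
  std::vector<int> cand = all_cols(m);
  std::vector<double> relimp(m, 0.0);
  std::vector<int> cnt(m, 0);
  NumericVector oob_mse(ntree, NA_REAL);
  NumericVector oob_pred_sum(n);
  IntegerVector oob_pred_cnt(n);
  std::vector<char> inbag(n);

  for (int t = 0; t < ntree; ++t) {
    IntegerVector sub = subsamples[t];
    IntegerVector perm = perms[t];
    std::vector<int> rows(sub.size());
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < sub.size(); ++i) {
      rows[i] = sub[i] - 1;
      inbag[rows[i]] = 1;
    }
    std::vector<int> oob;
    for (int r = 0; r < n; ++r) if (!inbag[r]) oob.push_back(r);

    std::vector<char> used(m, 0);
    GrowCfg cfg{0, mtry, min_node, max_depth, 1, 0.0, 0.0};
    Grower g(X, yy, cand, cfg, nullptr, &used);
    g.grow(rows, 0);

    if (oob.empty()) continue;
    const int no = (int)oob.size();
    std::vector<double> pred(no);
    double mse0 = 0.0;
    for (int i = 0; i < no; ++i) {
      pred[i] = predict_row(g.tree, X, oob[i]);
      oob_pred_sum[oob[i]] += pred[i];
      oob_pred_cnt[oob[i]]++;
      double d = yy[oob[i]] - pred[i];
      mse0 += d * d;
    }
    mse0 /= no;
    oob_mse[t] = mse0;
    if (mse0 <= 0.0) continue;

    for (int v = 0; v < m; ++v) {
      if (!used[v]) continue;
      double msep = 0.0;
      for (int i = 0; i < no; ++i) {
        double pv = (double)X(oob[perm[i] - 1], v);
        double p = predict_row(g.tree, X, oob[i], v, pv);
        double d = yy[oob[i]] - p;
        msep += d * d;
      }
      msep /= no;
      relimp[v] += (msep - mse0) / mse0;
      cnt[v]++;
    }
  }

  NumericVector score(m, 0.0);
  for (int v = 0; v < m; ++v) if (cnt[v] > 0) score[v] = 100.0 * relimp[v] / cnt[v];
  return List::create(_["score"] = score,
                      _["trees_used"] = IntegerVector(cnt.begin(), cnt.end()),
                      _["oob_mse"] = oob_mse,
                      _["oob_pred_sum"] = oob_pred_sum,
                      _["oob_pred_cnt"] = oob_pred_cnt);
}

// Least-squares gradient boosting; per-SNP relative influence is the sum of
// squared-error reductions over all splits on that SNP.
// [[Rcpp::export]]
List gbm_cpp(IntegerMatrix X, NumericVector y, IntegerVector train_rows,
             int ntree, double lr, int max_depth, int min_leaf,
             double subsample, IntegerVector valid_rows) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<double> yy(y.begin(), y.end());
  std::vector<int> train(train_rows.size());
  for (int i = 0; i < train_rows.size(); ++i) train[i] = train_rows[i] - 1;
  std::vector<int> valid(valid_rows.size());
  for (int i = 0; i < valid_rows.size(); ++i) valid[i] = valid_rows[i] - 1;

  double f0 = 0.0;
  for (int r : train) f0 += yy[r];
  f0 /= train.size();
  std::vector<double> f(n, f0);
  std::vector<double> resid(n, 0.0);
  for (int r : train) resid[r] = yy[r] - f[r];

  std::vector<double> influence(m, 0.0);
  std::vector<int> cand = all_cols(m);
  NumericVector train_mse(ntree), valid_mse(ntree);
  const int nsub = std::max(2, (int)std::floor(subsample * train.size()));

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> rows = (subsample < 1.0)
      ? sample_rows(train, nsub) : train;
    GrowCfg cfg{0, m, 2 * min_leaf - 1, max_depth, min_leaf, 0.0, 0.0};
    Grower g(X, resid, cand, cfg, &influence, nullptr);
    g.grow(rows, 0);

    double tm = 0.0;
    for (int r : train) {
      f[r] += lr * predict_row(g.tree, X, r);
      resid[r] = yy[r] - f[r];
      tm += resid[r] * resid[r];
    }
    train_mse[t] = tm / train.size();
    if (!valid.empty()) {
      double vm = 0.0;
      for (int r : valid) {
        f[r] += lr * predict_row(g.tree, X, r);
        double d = yy[r] - f[r];
        vm += d * d;
      }
      valid_mse[t] = vm / valid.size();
    }
  }

  return List::create(_["influence"] = NumericVector(influence.begin(), influence.end()),
                      _["fitted"] = NumericVector(f.begin(), f.end()),
                      _["train_mse"] = train_mse,
                      _["valid_mse"] = valid_mse,
                      _["init"] = f0);
}

// Second-order boosting with squared loss (gradient f - y, hessian 1),
// ridge lambda and split penalty gamma; per-SNP score is total gain.
// [[Rcpp::export]]
List xgb_cpp(IntegerMatrix X, NumericVector y, IntegerVector train_rows,
             int ntree, double lr, int max_depth, int min_leaf,
             double subsample, double lambda, double gamma,
             IntegerVector valid_rows) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<double> yy(y.begin(), y.end());
  std::vector<int> train(train_rows.size());
  for (int i = 0; i < train_rows.size(); ++i) train[i] = train_rows[i] - 1;
  std::vector<int> valid(valid_rows.size());
  for (int i = 0; i < valid_rows.size(); ++i) valid[i] = valid_rows[i] - 1;

  double f0 = 0.0;
  for (int r : train) f0 += yy[r];
  f0 /= train.size();
  std::vector<double> f(n, f0);
  std::vector<double> grad(n, 0.0);
  for (int r : train) grad[r] = f[r] - yy[r];

  std::vector<double> gain(m, 0.0);
  std::vector<int> cand = all_cols(m);
  NumericVector train_mse(ntree), valid_mse(ntree);
  const int nsub = std::max(2, (int)std::floor(subsample * train.size()));

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> rows = (subsample < 1.0)
      ? sample_rows(train, nsub) : train;
    GrowCfg cfg{1, m, 2 * min_leaf - 1, max_depth, min_leaf, lambda, gamma};
    Grower g(X, grad, cand, cfg, &gain, nullptr);
    g.grow(rows, 0);

    double tm = 0.0;
    for (int r : train) {
      f[r] += lr * predict_row(g.tree, X, r);
      grad[r] = f[r] - yy[r];
      tm += grad[r] * grad[r];
    }
    train_mse[t] = tm / train.size();
    if (!valid.empty()) {
      double vm = 0.0;
      for (int r : valid) {
        f[r] += lr * predict_row(g.tree, X, r);
        double d = yy[r] - f[r];
        vm += d * d;
      }
      valid_mse[t] = vm / valid.size();
    }
  }

  return List::create(_["gain"] = NumericVector(gain.begin(), gain.end()),
                      _["fitted"] = NumericVector(f.begin(), f.end()),
                      _["train_mse"] = train_mse,
                      _["valid_mse"] = valid_mse,
                      _["init"] = f0);
}
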