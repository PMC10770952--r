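#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Bagged CART forest for binary labels: bootstrap resamples, exhaustive
// Gini split search over a random feature subset at each node, majority
// vote prediction, cumulative weighted impurity-decrease importances.
// Uses R's RNG throughout so results are governed by set.seed().

namespace {

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;  // child indices, -1 for leaf
  std::vector<int> pred;         // majority class at node (ties -> 1)
  std::vector<int> nsamp;
};

inline double gini(int n1, int n) {
  if (n == 0) return 0.0;
  double p = (double)n1 / n;
  return 2.0 * p * (1.0 - p);
}

inline int runif_int(int n) { // uniform on 0..n-1 via R RNG
  int k = (int)(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Builder {
  const NumericMatrix &X;
  const IntegerVector &y;
  int mtry, min_leaf, max_depth, n_total;
  std::vector<double> &importance;
  TreeNodes t;
  std::vector<int> feat_pool;

  Builder(const NumericMatrix &X_, const IntegerVector &y_, int mtry_,
          int min_leaf_, int max_depth_, std::vector<double> &imp)
      : X(X_), y(y_), mtry(mtry_), min_leaf(min_leaf_), max_depth(max_depth_),
        n_total(0), importance(imp) {
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  int make_leaf(const std::vector<int> &idx, int n1) {
    int id = (int)t.feature.size();
    t.feature.push_back(-1);
    t.threshold.push_back(0.0);
    t.left.push_back(-1);
    t.right.push_back(-1);
    t.pred.push_back(2 * n1 >= (int)idx.size() ? 1 : 0);
    t.nsamp.push_back((int)idx.size());
    return id;
  }

  int grow(std::vector<int> &idx, int depth) {
    int n = (int)idx.size();
    int n1 = 0;
    for (int i = 0; i < n; ++i) n1 += y[idx[i]];
    if (n1 == 0 || n1 == n || n < 2 * min_leaf ||
        (max_depth >= 0 && depth >= max_depth))
      return make_leaf(idx, n1);

    // random feature subset (partial Fisher-Yates), then evaluated in
    // ascending index order so impurity ties resolve to the lower index
    int p = (int)feat_pool.size();
    int m = std::min(mtry, p);
    for (int k = 0; k < m; ++k) {
      int j = k + runif_int(p - k);
      std::swap(feat_pool[k], feat_pool[j]);
    }
    std::vector<int> feats(feat_pool.begin(), feat_pool.begin() + m);
    std::sort(feats.begin(), feats.end());

    double parent_imp = gini(n1, n);
    double best_gain = 0.0;
    int best_f = -1, best_cut = -1;
    double best_thr = 0.0;
    std::vector<int> ord(idx);

    for (size_t fk = 0; fk < feats.size(); ++fk) {
      int f = feats[fk];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        if (X(a, f) != X(b, f)) return X(a, f) < X(b, f);
        return a < b;
      });
      int left1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        left1 += y[ord[i]];
        if (X(ord[i], f) == X(ord[i + 1], f)) continue;
        int nl = i + 1, nrr = n - nl;
        if (nl < min_leaf || nrr < min_leaf) continue;
        double child =
            ((double)nl / n) * gini(left1, nl) +
            ((double)nrr / n) * gini(n1 - left1, nrr);
        double gain = parent_imp - child;
        if (gain > best_gain + 1e-12) { // strict: ties keep lower (f, thr)
          best_gain = gain;
          best_f = f;
          best_cut = i;
          best_thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
        }
      }
    }
    if (best_f < 0) return make_leaf(idx, n1);

    importance[best_f] += ((double)n / n_total) * best_gain;

    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      if (X(a, best_f) != X(b, best_f)) return X(a, best_f) < X(b, best_f);
      return a < b;
    });
    std::vector<int> lidx(idx.begin(), idx.begin() + best_cut + 1);
    std::vector<int> ridx(idx.begin() + best_cut + 1, idx.end());

    int id = (int)t.feature.size();
    t.feature.push_back(best_f);
    t.threshold.push_back(best_thr);
    t.left.push_back(-2);
    t.right.push_back(-2);
    t.pred.push_back(2 * n1 >= n ? 1 : 0);
    t.nsamp.push_back(n);
    int l = grow(lidx, depth + 1);
    int r = grow(ridx, depth + 1);
    t.left[id] = l;
    t.right[id] = r;
    return id;
  }
};

int tree_route(const IntegerVector &feature, const NumericVector &threshold,
               const IntegerVector &left, const IntegerVector &right,
               const IntegerVector &pred, const NumericMatrix &X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = X(row, feature[node]) <= threshold[node] ? left[node] : right[node];
  return pred[node];
}

} // namespace

// [[Rcpp::export(name = ".cpp_rf_train")]]
List cpp_rf_train(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                  int min_leaf, int max_depth, bool bootstrap) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> importance(p, 0.0);
  List trees(n_trees);
  IntegerMatrix inbag(n, n_trees); // resample multiplicities per tree
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = runif_int(n);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    for (int i = 0; i < n; ++i) ++inbag(idx[i], b);
    Builder bl(X, y, mtry, min_leaf, max_depth, importance);
    bl.n_total = n;
    bl.grow(idx, 0);
    trees[b] = List::create(
        _["feature"] = wrap(bl.t.feature), _["threshold"] = wrap(bl.t.threshold),
        _["left"] = wrap(bl.t.left), _["right"] = wrap(bl.t.right),
        _["pred"] = wrap(bl.t.pred), _["n"] = wrap(bl.t.nsamp));
  }
  return List::create(_["trees"] = trees, _["importance"] = wrap(importance),
                      _["inbag"] = inbag);
}

// [[Rcpp::export(name = ".cpp_rf_votes")]]
NumericVector cpp_rf_votes(List trees, NumericMatrix X) {
  int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"], pred = tr["pred"];
    for (int i = 0; i < n; ++i)
      out[i] += tree_route(feature, threshold, left, right, pred, X, i);
  }
  return out / (double)B;
}
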