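// Classification random forest for small binary expression problems.
// Gini-split CART trees grown to purity, bootstrap resampling, mtry random
// candidate features per node. Uses its own mt19937 stream so fits are
// reproducible from the seed passed in, independent of R's RNG state.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  // parallel node arrays; feature < 0 marks a leaf, pred in {0,1}
  std::vector<int> feature, left, right, pred;
  std::vector<double> threshold;
};

struct Builder {
  const NumericMatrix& X;  // n x d
  const IntegerVector& y;  // 0/1
  int mtry;
  std::mt19937& rng;
  Tree tree;
  std::vector<int> feat_pool;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
          std::mt19937& rng_)
      : X(X_), y(y_), mtry(mtry_), rng(rng_), feat_pool(X_.ncol()) {
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  int leaf(const std::vector<int>& idx) {
    int pos = 0;
    for (int i : idx) pos += y[i];
    int node = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(2 * pos >= (int)idx.size() ? 1 : 0);
    return node;
  }

  int grow(std::vector<int>& idx) {
    int n = (int)idx.size();
    int pos = 0;
    for (int i : idx) pos += y[i];
    if (n <= 1 || pos == 0 || pos == n) return leaf(idx);

    // sample mtry candidate features without replacement
    for (int j = 0; j < mtry; ++j) {
      std::uniform_int_distribution<int> pick(j, (int)feat_pool.size() - 1);
      std::swap(feat_pool[j], feat_pool[pick(rng)]);
    }

    double best_imp = 1e300, best_thr = 0.0;
    int best_feat = -1;
    std::vector<std::pair<double, int>> vals(n);
    for (int j = 0; j < mtry; ++j) {
      int f = feat_pool[j];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      int nl = 0, posl = 0;
      for (int i = 0; i + 1 < n; ++i) {
        ++nl;
        posl += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nr = n - nl, posr = pos - posl;
        double gl = (double)posl * (nl - posl) / nl;
        double gr = (double)posr * (nr - posr) / nr;
        double imp = gl + gr;  // weighted gini * n / 2, up to constants
        if (imp < best_imp) {
          best_imp = imp;
          best_feat = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return leaf(idx);  // all candidates constant

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) li.push_back(i);
      else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return leaf(idx);

    int node = (int)tree.feature.size();
    tree.feature.push_back(best_feat);
    tree.threshold.push_back(best_thr);
    tree.left.push_back(-2);   // patched below
    tree.right.push_back(-2);
    tree.pred.push_back(-1);
    int l = grow(li);
    int r = grow(ri);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

double tree_vote(const NumericMatrix& tr, const NumericVector& x) {
  int node = 0;
  while (tr(node, 0) >= 0) {
    int f = (int)tr(node, 0);
    node = (x[f] <= tr(node, 1)) ? (int)tr(node, 2) : (int)tr(node, 3);
  }
  return tr(node, 4);
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int seed) {
  int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> boot(0, n - 1);
  List forest(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Builder b(X, y, mtry, rng);
    b.grow(idx);
    int m = (int)b.tree.feature.size();
    NumericMatrix tr(m, 5);
    for (int i = 0; i < m; ++i) {
      tr(i, 0) = b.tree.feature[i];
      tr(i, 1) = b.tree.threshold[i];
      tr(i, 2) = b.tree.left[i];
      tr(i, 3) = b.tree.right[i];
      tr(i, 4) = b.tree.pred[i];
    }
    forest[t] = tr;
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  int n = X.nrow(), ntree = forest.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tr = forest[t];
    for (int i = 0; i < n; ++i) out[i] += tree_vote(tr, X(i, _));
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
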