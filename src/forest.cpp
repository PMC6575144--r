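// Compact random-forest classifier for narrative triage.
//
// Binary classification trees grown to purity (CART, Gini), per-tree
// balanced bootstrap of the two classes, per-split random feature subset
// of size mtry.  The forest "probability" is the fraction of trees whose
// leaf votes positive.  A dedicated mt19937 stream per tree keeps training
// reproducible for a given seed regardless of call order.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Forest {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right; // child node indices
  std::vector<int> pred;        // leaf class (valid when feature == -1)
  std::vector<int> offset;      // root node index per tree
};

struct Builder {
  const double* X; // column-major n x p
  int n, p, mtry, min_node;
  const int* y;
  std::mt19937* rng;
  Forest* out;
  std::vector<int> feat_pool;

  int build(std::vector<int>& idx) {
    int node = static_cast<int>(out->feature.size());
    out->feature.push_back(-1);
    out->threshold.push_back(0.0);
    out->left.push_back(-1);
    out->right.push_back(-1);
    out->pred.push_back(0);

    int m = static_cast<int>(idx.size());
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    int n0 = m - n1;
    if (n1 == 0 || n0 == 0 || m < std::max(2, min_node)) {
      out->pred[node] = (n1 > n0) ? 1 : 0;
      return node;
    }

    // draw mtry candidate features without replacement
    int k = std::min(mtry, p);
    for (int j = 0; j < k; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feat_pool[j], feat_pool[d(*rng)]);
    }

    double best_score = -1.0;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int> > vals(m);
    for (int j = 0; j < k; ++j) {
      int f = feat_pool[j];
      const double* col = X + static_cast<std::ptrdiff_t>(f) * n;
      for (int i = 0; i < m; ++i) vals[i] = std::make_pair(col[idx[i]], y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      if (vals[0].first == vals[m - 1].first) continue;
      // score = sum over sides of (c0^2 + c1^2)/side_n  (maximize)
      int l1 = 0;
      for (int i = 0; i < m - 1; ++i) {
        l1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int ln = i + 1, rn = m - ln;
        int l0 = ln - l1, r1 = n1 - l1, r0 = rn - r1;
        double score =
            (static_cast<double>(l0) * l0 + static_cast<double>(l1) * l1) / ln +
            (static_cast<double>(r0) * r0 + static_cast<double>(r1) * r1) / rn;
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    double parent =
        (static_cast<double>(n0) * n0 + static_cast<double>(n1) * n1) / m;
    if (best_f < 0 || best_score <= parent + 1e-12) {
      out->pred[node] = (n1 > n0) ? 1 : 0;
      return node;
    }

    std::vector<int> li, ri;
    li.reserve(m);
    ri.reserve(m);
    const double* col = X + static_cast<std::ptrdiff_t>(best_f) * n;
    for (int i : idx) {
      if (col[i] <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) { // numeric degeneracy guard
      out->pred[node] = (n1 > n0) ? 1 : 0;
      return node;
    }
    out->feature[node] = best_f;
    out->threshold[node] = best_thr;
    { std::vector<int>().swap(idx); } // free before recursing
    int lnode = build(li);
    { std::vector<int>().swap(li); }
    int rnode = build(ri);
    out->left[node] = lnode;
    out->right[node] = rnode;
    return node;
  }
};

} // namespace

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                  int min_node, bool balanced, int seed) {
  int n = X.nrow(), p = X.ncol();
  if (n_trees < 1) stop("n_trees must be >= 1");
  std::vector<int> pos, neg;
  for (int i = 0; i < n; ++i) (y[i] == 1 ? pos : neg).push_back(i);
  if (pos.empty() || neg.empty())
    stop("training set must contain both classes");

  Forest forest;
  forest.offset.reserve(n_trees);
  size_t m_bal = std::min(pos.size(), neg.size());

  for (int t = 0; t < n_trees; ++t) {
    std::mt19937 rng(static_cast<std::uint32_t>(seed) + 7919u * (t + 1));
    std::vector<int> idx;
    if (balanced) {
      idx.reserve(2 * m_bal);
      std::uniform_int_distribution<size_t> dp(0, pos.size() - 1);
      std::uniform_int_distribution<size_t> dn(0, neg.size() - 1);
      for (size_t i = 0; i < m_bal; ++i) idx.push_back(pos[dp(rng)]);
      for (size_t i = 0; i < m_bal; ++i) idx.push_back(neg[dn(rng)]);
    } else {
      idx.reserve(n);
      std::uniform_int_distribution<int> d(0, n - 1);
      for (int i = 0; i < n; ++i) idx.push_back(d(rng));
    }
    Builder b;
    b.X = REAL(X);
    b.n = n;
    b.p = p;
    b.mtry = mtry;
    b.min_node = min_node;
    b.y = INTEGER(y);
    b.rng = &rng;
    b.out = &forest;
    b.feat_pool.resize(p);
    for (int j = 0; j < p; ++j) b.feat_pool[j] = j;
    forest.offset.push_back(b.build(idx));
  }

  return List::create(
      _["feature"] = wrap(forest.feature),
      _["threshold"] = wrap(forest.threshold),
      _["left"] = wrap(forest.left),
      _["right"] = wrap(forest.right),
      _["pred"] = wrap(forest.pred),
      _["roots"] = wrap(forest.offset),
      _["n_trees"] = n_trees,
      _["p"] = p);
}

// Predict vote-share probabilities for rows stored in CSR form
// (row_ptr 0-based length n+1, col_idx 0-based, xval values).
// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List model, int n_rows, IntegerVector row_ptr,
                             IntegerVector col_idx, NumericVector xval) {
  IntegerVector feature = model["feature"];
  NumericVector threshold = model["threshold"];
  IntegerVector left = model["left"];
  IntegerVector right = model["right"];
  IntegerVector pred = model["pred"];
  IntegerVector roots = model["roots"];
  int p = as<int>(model["p"]);
  int n_trees = roots.size();

  std::vector<double> buf(p, 0.0);
  NumericVector out(n_rows);
  for (int i = 0; i < n_rows; ++i) {
    for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k) buf[col_idx[k]] = xval[k];
    int votes = 0;
    for (int t = 0; t < n_trees; ++t) {
      int node = roots[t];
      while (feature[node] >= 0) {
        node = (buf[feature[node]] <= threshold[node]) ? left[node]
                                                       : right[node];
      }
      votes += pred[node];
    }
    out[i] = static_cast<double>(votes) / n_trees;
    for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k) buf[col_idx[k]] = 0.0;
  }
  return out;
}
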