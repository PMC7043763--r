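// A compact random forest for binary pixel classification: CART trees with
// weighted Gini splits, bootstrap resampling and per-node feature
// subsampling.  RNG is a self-contained mt19937 draw so results are
// bit-reproducible across platforms for a given seed.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double unif01(std::mt19937& g) {
  return (g() >> 5) * (1.0 / 134217728.0);  // 27 random bits
}

struct TreeNode {
  int feat;       // -1 for leaf
  double thr;
  int left, right;
  double prob;    // positive-class weight fraction (leaves)
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  const NumericVector& w;
  int mtry, max_depth, min_leaf;
  std::mt19937& gen;
  std::vector<TreeNode> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_,
              const NumericVector& w_, int mtry_, int max_depth_,
              int min_leaf_, std::mt19937& gen_)
    : X(X_), y(y_), w(w_), mtry(mtry_), max_depth(max_depth_),
      min_leaf(min_leaf_), gen(gen_) {}

  int build(std::vector<int>& idx, int depth) {
    double wpos = 0, wtot = 0;
    for (int i : idx) { wtot += w[i]; if (y[i] == 1) wpos += w[i]; }
    double prob = wtot > 0 ? wpos / wtot : 0.5;
    int me = (int)nodes.size();
    nodes.push_back({-1, 0.0, -1, -1, prob});
    if ((int)idx.size() < 2 * min_leaf || depth >= max_depth ||
        prob <= 0.0 || prob >= 1.0)
      return me;

    const int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    // partial Fisher-Yates for mtry features
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + (int)(unif01(gen) * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }

    double best_gain = 1e-12;
    int best_feat = -1;
    double best_thr = 0;
    double parent_gini = 2.0 * prob * (1.0 - prob) * wtot;
    std::vector<int> ord(idx);
    for (int j = 0; j < m; ++j) {
      int f = feats[j];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        if (X(a, f) != X(b, f)) return X(a, f) < X(b, f);
        return a < b;
      });
      double lw = 0, lp = 0;
      for (size_t k = 0; k + 1 < ord.size(); ++k) {
        int i = ord[k];
        lw += w[i];
        if (y[i] == 1) lp += w[i];
        if (X(ord[k + 1], f) <= X(i, f)) continue;  // no split between equal values
        if ((int)(k + 1) < min_leaf || (int)(ord.size() - k - 1) < min_leaf) continue;
        double rw = wtot - lw, rp = wpos - lp;
        if (lw <= 0 || rw <= 0) continue;
        double gl = 2.0 * (lp / lw) * (1.0 - lp / lw) * lw;
        double gr = 2.0 * (rp / rw) * (1.0 - rp / rw) * rw;
        double gain = parent_gini - gl - gr;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (X(i, f) + X(ord[k + 1], f));
        }
      }
    }
    if (best_feat < 0) return me;
    std::vector<int> li, ri;
    for (int i : idx)
      (X(i, best_feat) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return me;
    nodes[me].feat = best_feat;
    nodes[me].thr = best_thr;
    int l = build(li, depth + 1);
    nodes[me].left = l;
    int r = build(ri, depth + 1);
    nodes[me].right = r;
    return me;
  }
};

// Fit a forest; returns a list of n_tree matrices with columns
// (feat, thr, left, right, prob), 0-based child indices, feat = -1 at leaves.
// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, IntegerVector y, NumericVector w,
                int n_tree, int mtry, int max_depth, int min_leaf, int seed) {
  const int n = X.nrow();
  std::mt19937 gen((unsigned)seed);
  // inverse-CDF weighted bootstrap (deterministic across platforms)
  std::vector<double> cw(n);
  double tot = 0;
  for (int i = 0; i < n; ++i) { tot += w[i]; cw[i] = tot; }
  List trees(n_tree);
  for (int t = 0; t < n_tree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      double u = unif01(gen) * tot;
      idx[i] = (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
      if (idx[i] >= n) idx[i] = n - 1;
    }
    TreeBuilder tb(X, y, w, mtry, max_depth, min_leaf, gen);
    tb.build(idx, 0);
    NumericMatrix tm(tb.nodes.size(), 5);
    for (size_t i = 0; i < tb.nodes.size(); ++i) {
      tm(i, 0) = tb.nodes[i].feat;
      tm(i, 1) = tb.nodes[i].thr;
      tm(i, 2) = tb.nodes[i].left;
      tm(i, 3) = tb.nodes[i].right;
      tm(i, 4) = tb.nodes[i].prob;
    }
    trees[t] = tm;
  }
  return trees;
}

// Mean positive-class probability over the forest.
// [[Rcpp::export]]
NumericVector cpp_rf_predict(List trees, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while ((int)tm(node, 0) >= 0) {
        int f = (int)tm(node, 0);
        node = (X(i, f) <= tm(node, 1)) ? (int)tm(node, 2) : (int)tm(node, 3);
      }
      out[i] += tm(node, 4);
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= trees.size();
  return out;
}
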