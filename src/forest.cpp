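// Class-weighted random forest with out-of-bag vote aggregation.
//
// CART trees grown on bootstrap samples; class weights enter both the
// split criterion (weighted Gini) and the leaf label (weighted majority).
// A self-contained xorshift RNG keyed by the config seed makes results
// reproducible across platforms independently of R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed * 2654435769ULL + 1ULL) {
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

struct Node {
  int feat;       // -1 for leaf
  double thr;
  int left, right;
  int leaf_class; // weighted-majority class (0-based), ties -> lowest index
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  const NumericVector& w; // per-class weights
  int K, mtry, min_node;
  XorShift& rng;
  std::vector<Node> nodes;
  std::vector<int> feat_pool;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_,
              const NumericVector& w_, int K_, int mtry_, int min_node_,
              XorShift& rng_)
      : X(X_), y(y_), w(w_), K(K_), mtry(mtry_), min_node(min_node_),
        rng(rng_) {
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  int leaf(const std::vector<double>& cw) {
    int best = 0;
    for (int k = 1; k < K; ++k)
      if (cw[k] > cw[best]) best = k;
    Node nd{-1, 0.0, -1, -1, best};
    nodes.push_back(nd);
    return static_cast<int>(nodes.size()) - 1;
  }

  // grow on sample indices (bootstrap rows, with multiplicity)
  int grow(std::vector<int>& idx) {
    int n = static_cast<int>(idx.size());
    std::vector<double> cw(K, 0.0);
    for (int i : idx) cw[y[i]] += w[y[i]];
    double total = 0.0, sumsq = 0.0;
    for (int k = 0; k < K; ++k) { total += cw[k]; sumsq += cw[k] * cw[k]; }
    double node_gini = 1.0 - sumsq / (total * total);
    if (n <= min_node || node_gini <= 0.0) return leaf(cw);

    // sample mtry features without replacement (partial Fisher-Yates)
    int p = X.ncol();
    for (int j = 0; j < mtry && j < p; ++j) {
      int r = j + rng.below(p - j);
      std::swap(feat_pool[j], feat_pool[r]);
    }

    int best_feat = -1;
    double best_thr = 0.0, best_score = -1.0;
    std::vector<int> ord(idx);
    std::vector<double> lw(K);
    for (int m = 0; m < mtry && m < p; ++m) {
      int f = feat_pool[m];
      std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      std::fill(lw.begin(), lw.end(), 0.0);
      double wl = 0.0, sql = 0.0;
      for (int i = 0; i + 1 < n; ++i) {
        int row = ord[i];
        int k = y[row];
        sql += w[k] * (2.0 * lw[k] + w[k]);
        lw[k] += w[k];
        wl += w[k];
        if (X(ord[i + 1], f) <= X(row, f)) continue; // not a valid cut
        double wr = total - wl;
        double sqr = 0.0;
        for (int k2 = 0; k2 < K; ++k2) {
          double rw = cw[k2] - lw[k2];
          sqr += rw * rw;
        }
        double score = sql / wl + sqr / wr; // maximizing <=> min weighted Gini
        // strict > keeps ties deterministic and predictions invariant under
        // rescaling all class weights by a power of two
        if (score > best_score) {
          best_score = score;
          best_feat = f;
          best_thr = 0.5 * (X(row, f) + X(ord[i + 1], f));
        }
      }
    }
    if (best_feat < 0) return leaf(cw);

    std::vector<int> left_idx, right_idx;
    left_idx.reserve(n);
    right_idx.reserve(n);
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) left_idx.push_back(i);
      else right_idx.push_back(i);
    }
    if (left_idx.empty() || right_idx.empty()) return leaf(cw);

    int self = static_cast<int>(nodes.size());
    Node nd{best_feat, best_thr, -1, -1, -1};
    nodes.push_back(nd);
    int l = grow(left_idx);
    int r = grow(right_idx);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }
};

int tree_predict(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (true) {
    int feat = static_cast<int>(tree(node, 0));
    if (feat < 0) return static_cast<int>(tree(node, 4));
    node = (X(row, feat) <= tree(node, 1))
               ? static_cast<int>(tree(node, 2))
               : static_cast<int>(tree(node, 3));
  }
}

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix m(static_cast<int>(nodes.size()), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feat;
    m(i, 1) = nodes[i].thr;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].leaf_class;
  }
  return m;
}

} // namespace

// [[Rcpp::export(rng = false)]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_class,
                  NumericVector class_weights, int n_trees, int mtry,
                  int min_node, int seed) {
  int n = X.nrow();
  XorShift rng(static_cast<uint64_t>(seed));
  IntegerMatrix votes(n, n_class);
  IntegerVector oob_trees(n);
  List trees(n_trees);
  std::vector<int> inbag(n);

  // class-weighted subsampling: class k contributes
  // round(0.632 * n_k * w_k / max(w)) rows drawn WITHOUT replacement
  // (0.632 = distinct fraction of an ordinary bootstrap). Equal weights
  // give every class its bootstrap-equivalent distinct support;
  // reciprocal-size weights give all classes the same distinct support
  // (balanced bags), which is what equalizes per-class vote geometry.
  // Sampling without replacement keeps out-of-bag coverage for every
  // class, unlike oversampling the minority with replacement.
  std::vector<std::vector<int>> class_rows(n_class);
  for (int i = 0; i < n; ++i) class_rows[y[i]].push_back(i);
  double wmax = 0.0;
  for (int k = 0; k < n_class; ++k)
    if (class_weights[k] > wmax) wmax = class_weights[k];
  std::vector<int> bag_count(n_class);
  for (int k = 0; k < n_class; ++k) {
    int nk = static_cast<int>(class_rows[k].size());
    double ck = 0.632 * nk * class_weights[k] / wmax;
    bag_count[k] = std::max(1, static_cast<int>(ck + 0.5));
    if (bag_count[k] >= nk && nk > 1) bag_count[k] = nk - 1;
  }

  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx;
    for (int k = 0; k < n_class; ++k) {
      std::vector<int>& rows = class_rows[k];
      int nk = static_cast<int>(rows.size());
      for (int j = 0; j < bag_count[k]; ++j) {
        int r = j + rng.below(nk - j); // partial Fisher-Yates, WOR
        std::swap(rows[j], rows[r]);
        idx.push_back(rows[j]);
        inbag[rows[j]] += 1;
      }
    }
    TreeBuilder tb(X, y, class_weights, n_class, mtry, min_node, rng);
    tb.grow(idx);
    NumericMatrix tree = pack_tree(tb.nodes);
    trees[t] = tree;
    for (int i = 0; i < n; ++i) {
      if (inbag[i] == 0) {
        votes(i, tree_predict(tree, X, i)) += 1;
        oob_trees[i] += 1;
      }
    }
  }
  return List::create(_["votes"] = votes, _["oob_trees"] = oob_trees,
                      _["trees"] = trees);
}

// [[Rcpp::export(rng = false)]]
IntegerMatrix rf_predict_votes_cpp(List trees, NumericMatrix X, int n_class) {
  int n = X.nrow();
  IntegerMatrix votes(n, n_class);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) votes(i, tree_predict(tree, X, i)) += 1;
  }
  return votes;
}
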