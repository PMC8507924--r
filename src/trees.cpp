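// CART tree growing for the in-package ensemble stack (random forest,
// logistic gradient boosting, RF-RFE). Only the per-tree work lives here;
// bootstrap draws, forest aggregation and the boosting loop stay in R.
//
// Conventions:
//   criterion 0 -> regression, variance (SSE) reduction splits
//   criterion 1 -> binary classification, Gini impurity decrease splits
//   max_depth 0 -> unlimited (internally capped)
//   mtry       -> candidate features sampled per node without replacement
//
// Determinism: feature subsampling uses a std::mt19937 seeded from
// (seed, stream) via std::seed_seq, independent of R's RNG.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct NodeRec {
  int feature;      // -1 for leaf
  double threshold; // midpoint split: x <= threshold goes left
  int left, right;  // child node ids, -1 for leaf
  double value;     // mean response over node samples
  int n;            // number of (possibly repeated) training samples
};

struct Grower {
  const NumericMatrix& X;
  const NumericVector& y;
  int criterion;
  int max_depth;
  int min_leaf;
  int mtry;
  std::mt19937 rng;
  std::vector<NodeRec> nodes;
  std::vector<int> leaf_of; // per training sample: leaf node id
  std::vector<double> importance;
  std::vector<int> feat_pool;

  Grower(const NumericMatrix& X_, const NumericVector& y_, int crit,
         int maxd, int minl, int mtry_, unsigned int seed, unsigned int stream)
      : X(X_), y(y_), criterion(crit), max_depth(maxd <= 0 ? 100000 : maxd),
        min_leaf(minl < 1 ? 1 : minl), mtry(mtry_) {
    std::seed_seq ss{seed, stream, 0x9e3779b9u};
    rng.seed(ss);
    importance.assign(X.ncol(), 0.0);
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  // node impurity * n: SSE for regression, n * gini for classification
  static double impurity_times_n(double sum, double sumsq, double n,
                                 int criterion) {
    if (n <= 0.0) return 0.0;
    if (criterion == 0) return sumsq - sum * sum / n;
    double p = sum / n; // y in {0,1}: sum = count of class 1
    return n * 2.0 * p * (1.0 - p);
  }

  int grow(std::vector<int>& samp, int depth) {
    int id = (int)nodes.size();
    nodes.push_back(NodeRec());
    NodeRec& nd = nodes[id];
    int n = (int)samp.size();
    double sum = 0.0, sumsq = 0.0;
    for (int i : samp) { sum += y[i]; sumsq += y[i] * y[i]; }
    nd.feature = -1;
    nd.threshold = NA_REAL;
    nd.left = nd.right = -1;
    nd.value = sum / n;
    nd.n = n;

    double node_imp = impurity_times_n(sum, sumsq, (double)n, criterion);
    bool can_split = depth < max_depth && n >= 2 * min_leaf && node_imp > 1e-12;

    int best_f = -1, best_pos = -1;
    double best_gain = 1e-12, best_thr = 0.0;
    std::vector<int> ord;
    std::vector<int> best_ord;

    if (can_split) {
      // sample mtry candidate features without replacement
      int p = (int)feat_pool.size();
      int m = mtry < 1 ? 1 : (mtry > p ? p : mtry);
      for (int j = 0; j < m; ++j) {
        std::uniform_int_distribution<int> pick(j, p - 1);
        std::swap(feat_pool[j], feat_pool[pick(rng)]);
      }
      ord.resize(n);
      for (int jj = 0; jj < m; ++jj) {
        int f = feat_pool[jj];
        for (int i = 0; i < n; ++i) ord[i] = samp[i];
        std::sort(ord.begin(), ord.end(), [&](int a, int b) {
          double xa = X(a, f), xb = X(b, f);
          if (xa != xb) return xa < xb;
          return a < b;
        });
        double lsum = 0.0, lsumsq = 0.0;
        for (int i = 0; i < n - 1; ++i) {
          double yi = y[ord[i]];
          lsum += yi; lsumsq += yi * yi;
          int nl = i + 1, nr = n - nl;
          if (nl < min_leaf || nr < min_leaf) continue;
          double xl = X(ord[i], f), xr = X(ord[i + 1], f);
          if (xl >= xr) continue; // not a distinct-value boundary
          double gain = node_imp -
              impurity_times_n(lsum, lsumsq, (double)nl, criterion) -
              impurity_times_n(sum - lsum, sumsq - lsumsq, (double)nr,
                               criterion);
          if (gain > best_gain) {
            best_gain = gain;
            best_f = f;
            best_pos = i;
            best_thr = xl + (xr - xl) / 2.0;
            best_ord = ord;
          }
        }
      }
    }

    if (best_f < 0) {
      for (int i : samp) leaf_of[i] = id;
      return id;
    }

    importance[best_f] += best_gain;
    std::vector<int> left_s(best_ord.begin(), best_ord.begin() + best_pos + 1);
    std::vector<int> right_s(best_ord.begin() + best_pos + 1, best_ord.end());
    // free before recursing
    { std::vector<int>().swap(best_ord); std::vector<int>().swap(samp); }
    int lid = grow(left_s, depth + 1);
    int rid = grow(right_s, depth + 1);
    nodes[id].feature = best_f;
    nodes[id].threshold = best_thr;
    nodes[id].left = lid;
    nodes[id].right = rid;
    return id;
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_grow_tree")]]
List cpp_grow_tree(NumericMatrix X, NumericVector y, IntegerVector rows,
                   int criterion, int max_depth, int min_leaf, int mtry,
                   int seed, int stream) {
  int n = rows.size();
  if (n < 1) stop("no training samples");
  Grower g(X, y, criterion, max_depth, min_leaf, mtry,
           (unsigned int)seed, (unsigned int)stream);
  g.leaf_of.assign(X.nrow(), -1);
  std::vector<int> samp(n);
  for (int i = 0; i < n; ++i) samp[i] = rows[i] - 1; // 1-based from R
  g.grow(samp, 0);

  int nn = (int)g.nodes.size();
  IntegerVector feature(nn), left(nn), right(nn), nnode(nn);
  NumericVector threshold(nn), value(nn);
  for (int i = 0; i < nn; ++i) {
    feature[i] = g.nodes[i].feature < 0 ? NA_INTEGER : g.nodes[i].feature + 1;
    threshold[i] = g.nodes[i].threshold;
    left[i] = g.nodes[i].left < 0 ? NA_INTEGER : g.nodes[i].left + 1;
    right[i] = g.nodes[i].right < 0 ? NA_INTEGER : g.nodes[i].right + 1;
    value[i] = g.nodes[i].value;
    nnode[i] = g.nodes[i].n;
  }
  IntegerVector leaf_of(X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    leaf_of[i] = g.leaf_of[i] < 0 ? NA_INTEGER : g.leaf_of[i] + 1;
  return List::create(
      _["feature"] = feature, _["threshold"] = threshold, _["left"] = left,
      _["right"] = right, _["value"] = value, _["n"] = nnode,
      _["leaf_of"] = leaf_of,
      _["importance"] = NumericVector(g.importance.begin(),
                                      g.importance.end()));
}

// [[Rcpp::export(name = ".cpp_predict_tree")]]
List cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  IntegerVector leaf(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] != NA_INTEGER) {
      int f = feature[node] - 1;
      node = (X(i, f) <= threshold[node] ? left[node] : right[node]) - 1;
    }
    out[i] = value[node];
    leaf[i] = node + 1;
  }
  return List::create(_["value"] = out, _["leaf"] = leaf);
}
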