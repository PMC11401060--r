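// Deterministic weighted gradient-boosted trees for binary classification
// (logistic loss). Exact greedy splits on weighted squared-error reduction
// of the current gradients, Newton leaf updates, no subsampling: fits are
// exactly reproducible for fixed data and weights.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // child node ids, -1 for leaf
  double value;     // leaf value (Newton step)
};

struct TreeBuilder {
  const NumericMatrix& X;
  const std::vector<double>& grad;   // residuals y - p
  const std::vector<double>& hess;   // p (1 - p)
  const std::vector<double>& w;
  int max_depth;
  int min_leaf;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const std::vector<double>& g,
              const std::vector<double>& h, const std::vector<double>& w_,
              int depth, int min_leaf_)
      : X(X_), grad(g), hess(h), w(w_), max_depth(depth),
        min_leaf(min_leaf_) {}

  double leaf_value(const std::vector<int>& idx) const {
    double num = 0.0, den = 0.0;
    for (int i : idx) {
      num += w[i] * grad[i];
      den += w[i] * hess[i];
    }
    double v = num / (den + 1e-12);
    if (v > 8.0) v = 8.0;
    if (v < -8.0) v = -8.0;
    return v;
  }

  int build(std::vector<int>& idx, int depth) {
    int id = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
    bool can_split = depth < max_depth && (int)idx.size() >= 2 * min_leaf;
    double best_gain = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;
    if (can_split) {
      double tot_wr = 0.0, tot_w = 0.0;
      for (int i : idx) {
        tot_wr += w[i] * grad[i];
        tot_w += w[i];
      }
      double base = tot_wr * tot_wr / (tot_w + 1e-12);
      int p = X.ncol();
      std::vector<std::pair<double, int> > vals(idx.size());
      for (int f = 0; f < p; ++f) {
        for (size_t k = 0; k < idx.size(); ++k) {
          vals[k] = std::make_pair(X(idx[k], f), idx[k]);
        }
        std::sort(vals.begin(), vals.end());
        double l_wr = 0.0, l_w = 0.0;
        for (size_t k = 0; k + 1 < vals.size(); ++k) {
          int i = vals[k].second;
          l_wr += w[i] * grad[i];
          l_w += w[i];
          if (vals[k + 1].first <= vals[k].first) continue;  // tie block
          if ((int)(k + 1) < min_leaf ||
              (int)(vals.size() - k - 1) < min_leaf) continue;
          double r_wr = tot_wr - l_wr, r_w = tot_w - l_w;
          double gain = l_wr * l_wr / (l_w + 1e-12) +
                        r_wr * r_wr / (r_w + 1e-12) - base;
          if (gain > best_gain + 1e-12) {
            best_gain = gain;
            best_feat = f;
            best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
          }
        }
      }
    }
    if (best_feat < 0) {
      nodes[id].value = leaf_value(idx);
      return id;
    }
    std::vector<int> left_idx, right_idx;
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) left_idx.push_back(i);
      else right_idx.push_back(i);
    }
    nodes[id].feature = best_feat;
    nodes[id].threshold = best_thr;
    nodes[id].left = build(left_idx, depth + 1);
    nodes[id].right = build(right_idx, depth + 1);
    return id;
  }
};

static double tree_predict_row(const NumericMatrix& tree,
                               const NumericMatrix& X, int row) {
  int node = 0;
  while (true) {
    int feat = (int)tree(node, 0);
    if (feat < 0) return tree(node, 4);
    node = (X(row, feat) <= tree(node, 1)) ? (int)tree(node, 2)
                                           : (int)tree(node, 3);
  }
}

// [[Rcpp::export(name = ".gbm_fit_cpp")]]
List gbm_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                 int n_estimators, double learning_rate, int max_depth,
                 int min_samples_leaf) {
  int n = X.nrow();
  double wsum = 0.0, wy = 0.0;
  for (int i = 0; i < n; ++i) {
    wsum += w[i];
    wy += w[i] * y[i];
  }
  double p0 = std::min(1 - 1e-6, std::max(1e-6, wy / wsum));
  double init = std::log(p0 / (1.0 - p0));

  std::vector<double> F(n, init), grad(n), hess(n), wv(w.begin(), w.end());
  List trees(n_estimators);
  for (int m = 0; m < n_estimators; ++m) {
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-F[i]));
      grad[i] = y[i] - p;
      hess[i] = std::max(p * (1.0 - p), 1e-9);
    }
    TreeBuilder tb(X, grad, hess, wv, max_depth, min_samples_leaf);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    tb.build(idx, 0);
    NumericMatrix tree((int)tb.nodes.size(), 5);
    for (size_t k = 0; k < tb.nodes.size(); ++k) {
      tree(k, 0) = tb.nodes[k].feature;
      tree(k, 1) = tb.nodes[k].threshold;
      tree(k, 2) = tb.nodes[k].left;
      tree(k, 3) = tb.nodes[k].right;
      tree(k, 4) = tb.nodes[k].value;
    }
    for (int i = 0; i < n; ++i) {
      F[i] += learning_rate * tree_predict_row(tree, X, i);
    }
    trees[m] = tree;
  }
  return List::create(_["init"] = init, _["trees"] = trees,
                      _["learning_rate"] = learning_rate);
}

// [[Rcpp::export(name = ".gbm_predict_cpp")]]
NumericVector gbm_predict_cpp(List model, NumericMatrix X) {
  double init = as<double>(model["init"]);
  double lr = as<double>(model["learning_rate"]);
  List trees = model["trees"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double F = init;
    for (int m = 0; m < trees.size(); ++m) {
      NumericMatrix tree = trees[m];
      F += lr * tree_predict_row(tree, X, i);
    }
    out[i] = 1.0 / (1.0 + std::exp(-F));
  }
  return out;
}
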