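// CART trees plus the two ensemble learners built on them:
//  - probability random forest (gini splits, bootstrap bagging, mtry)
//  - stochastic gradient boosting for bernoulli response (SSE trees on the
//    gradient with Newton leaf updates, bag_fraction row subsampling)
// All randomness flows through R's RNG so set.seed() in R gives bit-stable
// fits; trees are returned as flat numeric matrices so fitted models survive
// serialization as plain lists.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Node {
  int feature;      // -1 for leaf
  double threshold; // x <= threshold goes left
  int left, right;  // node indices, -1 for leaf
  double value;     // leaf prediction
};

// Grow one tree on rows `idx` of X. criterion: 0 = gini on y in {0,1},
// 1 = SSE on continuous y. Leaf value: class-1 fraction (gini) or mean (sse).
// Splits are exact greedy over mtry features sampled without replacement via
// R's RNG. Returns nodes; also fills leaf_of with the leaf node id per row of
// idx (used by the booster for Newton leaf updates).
static void grow_tree(const NumericMatrix& X, const NumericVector& y,
                      std::vector<int>& idx, int lo, int hi, int depth,
                      int max_depth, int min_node, int mtry, int criterion,
                      std::vector<Node>& nodes, std::vector<int>& leaf_of,
                      const std::vector<int>& row_slot) {
  int n = hi - lo;
  int p = X.ncol();
  double sum = 0.0, sum2 = 0.0;
  for (int k = lo; k < hi; ++k) { double v = y[idx[k]]; sum += v; sum2 += v * v; }
  double mean = sum / n;

  bool make_leaf = (n < 2 * min_node) || (max_depth > 0 && depth >= max_depth);
  if (!make_leaf) {
    // pure node?
    double imp = (criterion == 0) ? mean * (1.0 - mean) : (sum2 - sum * sum / n);
    if (imp <= 1e-12) make_leaf = true;
  }

  int best_f = -1, best_pos = -1;
  double best_thr = 0.0, best_gain = 1e-12;
  static thread_local std::vector<int> ord;
  if (!make_leaf) {
    // sample mtry feature indices without replacement (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int pick = j + (int)std::floor(unif_rand() * (p - j));
      if (pick >= p) pick = p - 1;
      std::swap(feats[j], feats[pick]);
    }
    std::vector<int> order(idx.begin() + lo, idx.begin() + hi);
    for (int jj = 0; jj < m; ++jj) {
      int f = feats[jj];
      std::sort(order.begin(), order.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      // prefix sums scan
      double ls = 0.0, ls2 = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        double v = y[order[k]];
        ls += v; ls2 += v * v;
        int nl = k + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double xk = X(order[k], f), xk1 = X(order[k + 1], f);
        if (xk1 <= xk) continue; // no distinct boundary
        double rs = sum - ls;
        double gain;
        if (criterion == 0) {
          double pl = ls / nl, pr = rs / nr;
          double parent = n * mean * (1.0 - mean);
          gain = parent - nl * pl * (1.0 - pl) - nr * pr * (1.0 - pr);
        } else {
          double parent = sum2 - sum * sum / n;
          double sseL = ls2 - ls * ls / nl;
          double rs2 = sum2 - ls2;
          double sseR = rs2 - rs * rs / nr;
          gain = parent - sseL - sseR;
        }
        if (gain > best_gain) {
          best_gain = gain; best_f = f; best_pos = k;
          best_thr = 0.5 * (xk + xk1);
        }
      }
    }
  }

  int me = (int)nodes.size();
  nodes.push_back(Node());
  if (make_leaf || best_f < 0) {
    nodes[me] = { -1, 0.0, -1, -1, mean };
    for (int k = lo; k < hi; ++k) leaf_of[row_slot[idx[k]]] = me;
    return;
  }
  // partition idx[lo,hi) in place by the chosen split
  int mid = lo;
  for (int k = lo; k < hi; ++k)
    if (X(idx[k], best_f) <= best_thr) std::swap(idx[k], idx[mid++]);
  nodes[me].feature = best_f;
  nodes[me].threshold = best_thr;
  nodes[me].value = mean;
  nodes[me].left = (int)nodes.size();
  grow_tree(X, y, idx, lo, mid, depth + 1, max_depth, min_node, mtry,
            criterion, nodes, leaf_of, row_slot);
  nodes[me].right = (int)nodes.size();
  grow_tree(X, y, idx, mid, hi, depth + 1, max_depth, min_node, mtry,
            criterion, nodes, leaf_of, row_slot);
}

static NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix out(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    out(i, 0) = nodes[i].feature;
    out(i, 1) = nodes[i].threshold;
    out(i, 2) = nodes[i].left;
    out(i, 3) = nodes[i].right;
    out(i, 4) = nodes[i].value;
  }
  return out;
}

static double tree_score(const NumericMatrix& tr, const NumericMatrix& X, int row) {
  int node = 0;
  while (tr(node, 0) >= 0) {
    int f = (int)tr(node, 0);
    node = (X(row, f) <= tr(node, 1)) ? (int)tr(node, 2) : (int)tr(node, 3);
  }
  return tr(node, 4);
}

// [[Rcpp::export(name = ".cpp_rf_fit")]]
List cpp_rf_fit(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_node, int max_depth) {
  RNGScope scope;
  int n = X.nrow();
  List trees(ntree);
  std::vector<int> row_slot(n);
  for (int i = 0; i < n; ++i) row_slot[i] = i;
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int pick = (int)std::floor(unif_rand() * n);
      if (pick >= n) pick = n - 1;
      idx[i] = pick;
    }
    std::vector<Node> nodes;
    std::vector<int> leaf_of(n, 0);
    grow_tree(X, y, idx, 0, n, 0, max_depth, min_node, mtry, 0,
              nodes, leaf_of, row_slot);
    trees[t] = pack_tree(nodes);
  }
  return trees;
}

// [[Rcpp::export(name = ".cpp_forest_predict")]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tr = trees[t];
    for (int i = 0; i < n; ++i) out[i] += tree_score(tr, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

static double bernoulli_deviance(const NumericVector& y, const std::vector<double>& F) {
  double d = 0.0;
  for (size_t i = 0; i < F.size(); ++i) {
    double p = 1.0 / (1.0 + std::exp(-F[i]));
    p = std::min(1.0 - 1e-12, std::max(1e-12, p));
    d += -2.0 * (y[i] * std::log(p) + (1.0 - y[i]) * std::log(1.0 - p));
  }
  return d / F.size();
}

// Stochastic gradient boosting, bernoulli loss. Returns the tree sequence,
// the intercept f0 (logit of the training prevalence), and the per-iteration
// mean holdout deviance so R can pick the stopping iteration.
// [[Rcpp::export(name = ".cpp_brt_fit")]]
List cpp_brt_fit(NumericMatrix X, NumericVector y,
                 NumericMatrix Xv, NumericVector yv,
                 int n_trees, double learning_rate, double bag_fraction,
                 int max_depth, int min_node) {
  RNGScope scope;
  int n = X.nrow(), nv = Xv.nrow(), p = X.ncol();
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(1.0 - 1e-6, std::max(1e-6, ybar));
  double f0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> F(n, f0), Fv(nv, f0);
  std::vector<int> row_slot(n);
  for (int i = 0; i < n; ++i) row_slot[i] = i;
  int nbag = std::max(2 * min_node, (int)std::floor(bag_fraction * n));
  List trees(n_trees);
  NumericVector valid_dev(n_trees);
  NumericVector z(n);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<double> prob(n);
    for (int i = 0; i < n; ++i) {
      prob[i] = 1.0 / (1.0 + std::exp(-F[i]));
      z[i] = y[i] - prob[i];
    }
    // bag: sample nbag rows without replacement (partial Fisher-Yates)
    std::vector<int> perm(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = 0; i < nbag; ++i) {
      int pick = i + (int)std::floor(unif_rand() * (n - i));
      if (pick >= n) pick = n - 1;
      std::swap(perm[i], perm[pick]);
    }
    std::vector<int> idx(perm.begin(), perm.begin() + nbag);
    std::vector<Node> nodes;
    std::vector<int> leaf_of(n, -1);
    grow_tree(X, z, idx, 0, nbag, 0, max_depth, min_node, p, 1,
              nodes, leaf_of, row_slot);
    // Newton leaf values gamma = sum(z) / sum(p (1-p)) over bagged rows
    std::vector<double> num(nodes.size(), 0.0), den(nodes.size(), 0.0);
    for (int k = 0; k < nbag; ++k) {
      int i = idx[k], lf = leaf_of[i];
      if (lf < 0) continue;
      num[lf] += z[i];
      den[lf] += prob[i] * (1.0 - prob[i]);
    }
    for (size_t j = 0; j < nodes.size(); ++j)
      if (nodes[j].feature < 0)
        nodes[j].value = (den[j] > 1e-12) ? num[j] / den[j] : 0.0;
    NumericMatrix tr = pack_tree(nodes);
    trees[t] = tr;
    for (int i = 0; i < n; ++i) F[i] += learning_rate * tree_score(tr, X, i);
    for (int i = 0; i < nv; ++i) Fv[i] += learning_rate * tree_score(tr, Xv, i);
    valid_dev[t] = (nv > 0) ? bernoulli_deviance(yv, Fv) : bernoulli_deviance(y, F);
  }
  return List::create(_["trees"] = trees, _["f0"] = f0,
                      _["valid_deviance"] = valid_dev);
}

// [[Rcpp::export(name = ".cpp_brt_predict")]]
NumericVector cpp_brt_predict(List trees, double f0, double learning_rate,
                              int n_use, NumericMatrix X) {
  int n = X.nrow();
  NumericVector F(n, f0);
  int T = std::min((int)trees.size(), n_use);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tr = trees[t];
    for (int i = 0; i < n; ++i) F[i] += learning_rate * tree_score(tr, X, i);
  }
  for (int i = 0; i < n; ++i) F[i] = 1.0 / (1.0 + std::exp(-F[i]));
  return F;
}
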