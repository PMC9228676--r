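// Binary classification random forest: bootstrap-aggregated CART trees with
// Gini splitting, mtry feature subsampling, out-of-bag votes and
// mean-decrease-Gini importance. Uses R's RNG so results are reproducible
// under set.seed().
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  // node arrays; var = -1 marks a leaf
  std::vector<int> var, left, right, pred;
  std::vector<double> split;
};

inline double gini_sum(int n0, int n1) {
  // n * GiniImpurity = n - (n0^2 + n1^2) / n
  double n = n0 + n1;
  if (n <= 0) return 0.0;
  return n - ((double)n0 * n0 + (double)n1 * n1) / n;
}

inline int runif_int(int n) {
  // uniform draw from 0..n-1 via R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;  // 0/1
  int mtry, nodesize;
  Tree tree;
  std::vector<double> importance;  // per feature, summed Gini decrease
  std::vector<int> feat_pool;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
          int nodesize_)
      : X(X_), y(y_), mtry(mtry_), nodesize(nodesize_),
        importance(X_.ncol(), 0.0), feat_pool(X_.ncol()) {
    for (int j = 0; j < X_.ncol(); ++j) feat_pool[j] = j;
  }

  int grow(std::vector<int>& idx) {
    int n = idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    int n0 = n - n1;
    int node = tree.var.size();
    tree.var.push_back(-1);
    tree.split.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    // majority vote; ties go to class 0 (the "continue down the cascade" side)
    tree.pred.push_back(n1 > n0 ? 1 : 0);
    if (n0 == 0 || n1 == 0 || n <= nodesize) return node;

    double parent = gini_sum(n0, n1);
    double best_dec = 1e-12;  // require a strictly positive decrease
    int best_f = -1;
    double best_split = 0.0;

    // examine features in random order until mtry NON-constant candidates
    // have been scored (constant-in-node features do not count against
    // mtry, so a node only becomes a leaf early if it is truly unsplittable)
    int p = feat_pool.size();
    for (int k = 0; k < p - 1; ++k) {
      int j = k + runif_int(p - k);
      std::swap(feat_pool[k], feat_pool[j]);
    }
    std::vector<std::pair<double, int>> vals(n);
    int tried = 0;
    for (int k = 0; k < p && tried < mtry; ++k) {
      int f = feat_pool[k];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;  // constant
      ++tried;
      int l0 = 0, l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        if (vals[i].second) ++l1; else ++l0;
        if (vals[i].first == vals[i + 1].first) continue;
        double dec = parent - gini_sum(l0, l1) - gini_sum(n0 - l0, n1 - l1);
        if (dec > best_dec) {
          best_dec = dec;
          best_f = f;
          best_split = vals[i].first +
                       (vals[i + 1].first - vals[i].first) / 2.0;
        }
      }
    }
    if (best_f < 0) return node;

    std::vector<int> left_idx, right_idx;
    left_idx.reserve(n);
    right_idx.reserve(n);
    for (int i : idx) {
      if (X(i, best_f) <= best_split) left_idx.push_back(i);
      else right_idx.push_back(i);
    }
    if (left_idx.empty() || right_idx.empty()) return node;  // degenerate
    importance[best_f] += best_dec;
    tree.var[node] = best_f;
    tree.split[node] = best_split;
    int l = grow(left_idx);
    tree.left[node] = l;
    int r = grow(right_idx);
    tree.right[node] = r;
    return node;
  }
};

inline int tree_predict(const Tree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.var[node] >= 0)
    node = X(row, t.var[node]) <= t.split[node] ? t.left[node] : t.right[node];
  return t.pred[node];
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int nodesize) {
  int n = X.nrow(), p = X.ncol();
  List trees(ntree);
  NumericVector importance(p);
  IntegerMatrix oob_votes(n, 2);
  std::vector<char> inbag(n);
  for (int b = 0; b < ntree; ++b) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      idx[i] = runif_int(n);
      inbag[idx[i]] = 1;
    }
    Builder bl(X, y, mtry, nodesize);
    bl.grow(idx);
    for (int j = 0; j < p; ++j) importance[j] += bl.importance[j];
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob_votes(i, tree_predict(bl.tree, X, i)) += 1;
    trees[b] = List::create(
        _["var"] = IntegerVector(bl.tree.var.begin(), bl.tree.var.end()),
        _["split"] = NumericVector(bl.tree.split.begin(), bl.tree.split.end()),
        _["left"] = IntegerVector(bl.tree.left.begin(), bl.tree.left.end()),
        _["right"] = IntegerVector(bl.tree.right.begin(), bl.tree.right.end()),
        _["pred"] = IntegerVector(bl.tree.pred.begin(), bl.tree.pred.end()));
  }
  for (int j = 0; j < p; ++j) importance[j] /= ntree;
  return List::create(_["trees"] = trees, _["importance"] = importance,
                      _["oob_votes"] = oob_votes);
}

// [[Rcpp::export]]
IntegerMatrix rf_votes_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  IntegerMatrix votes(n, 2);
  for (int b = 0; b < ntree; ++b) {
    List tl = trees[b];
    Tree t;
    t.var = as<std::vector<int>>(tl["var"]);
    t.split = as<std::vector<double>>(tl["split"]);
    t.left = as<std::vector<int>>(tl["left"]);
    t.right = as<std::vector<int>>(tl["right"]);
    t.pred = as<std::vector<int>>(tl["pred"]);
    for (int i = 0; i < n; ++i) votes(i, tree_predict(t, X, i)) += 1;
  }
  return votes;
}
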