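// Classification random forest (Breiman): bootstrap-resampled CART trees
// with Gini-impurity splits over mtry randomly sampled candidate
// features, majority-vote leaves and accumulated Gini-decrease
// importance. Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // x <= threshold goes left
  std::vector<int> left, right;
  std::vector<double> vote;      // leaf vote for class 1
};

inline double gini(int n1, int n) {
  if (n == 0) return 0.0;
  double p = (double)n1 / n;
  return 2.0 * p * (1.0 - p);
}

int buildNode(const NumericMatrix& X, const IntegerVector& y,
              std::vector<int>& idx, int lo, int hi, int mtry,
              int nodesize, Tree& tree, std::vector<double>& importance) {
  int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];

  int node = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.vote.push_back(n1 * 2 >= n ? 1.0 : 0.0);

  if (n <= nodesize || n1 == 0 || n1 == n) return node;

  int p = X.ncol();
  // sample mtry features without replacement
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }

  double parent_imp = gini(n1, n);
  double best_dec = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int>> vals(n);
  for (int j = 0; j < m; ++j) {
    int f = feats[j];
    for (int i = 0; i < n; ++i) {
      int r = idx[lo + i];
      vals[i] = std::make_pair(X(r, f), y[r]);
    }
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    int nl = 0, nl1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      ++nl;
      nl1 += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      int nr = n - nl, nr1 = n1 - nl1;
      double dec = n * parent_imp - nl * gini(nl1, nl) - nr * gini(nr1, nr);
      if (dec > best_dec) {
        best_dec = dec;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }

  if (best_f < 0) return node;

  // partition idx[lo..hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;

  importance[best_f] += best_dec;
  tree.feature[node] = best_f;
  tree.threshold[node] = best_thr;
  int l = buildNode(X, y, idx, lo, mid, mtry, nodesize, tree, importance);
  int r = buildNode(X, y, idx, mid, hi, mtry, nodesize, tree, importance);
  tree.left[node] = l;
  tree.right[node] = r;
  return node;
}

double predictTree(const Tree& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree.feature[node] >= 0)
    node = (X(row, tree.feature[node]) <= tree.threshold[node])
               ? tree.left[node] : tree.right[node];
  return tree.vote[node];
}

} // namespace

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(NumericMatrix X, IntegerVector y, int ntree, int mtry,
            int nodesize) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> importance(p, 0.0);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
    }
    Tree tree;
    buildNode(X, y, idx, 0, n, mtry, nodesize, tree, importance);
    trees[t] = List::create(_["feature"] = wrap(tree.feature),
                            _["threshold"] = wrap(tree.threshold),
                            _["left"] = wrap(tree.left),
                            _["right"] = wrap(tree.right),
                            _["vote"] = wrap(tree.vote));
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / ntree;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict(List model, NumericMatrix X) {
  List trees = model["trees"];
  int ntree = trees.size(), n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    List tl = trees[t];
    Tree tree;
    tree.feature = as<std::vector<int>>(tl["feature"]);
    tree.threshold = as<std::vector<double>>(tl["threshold"]);
    tree.left = as<std::vector<int>>(tl["left"]);
    tree.right = as<std::vector<int>>(tl["right"]);
    tree.vote = as<std::vector<double>>(tl["vote"]);
    for (int i = 0; i < n; ++i) out[i] += predictTree(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
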