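#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Flat tree layout, one row per node (preorder, children after parent):
//   col 0 feature   split feature (1-based), 0 for leaf
//   col 1 threshold split point (x <= threshold goes left), NA-like 0 for leaf
//   col 2 left      1-based row of left child, 0 for leaf
//   col 3 right     1-based row of right child, 0 for leaf
//   col 4 label     majority class (1..K) of training samples at the node;
//                   stored at every node so subtrees can be collapsed later
//   col 5 depth     root = 1
//   col 6 n         training samples reaching the node

struct FlatNode {
  int feature;
  double threshold;
  int left, right, label, depth, n;
};

static int majority_label(const std::vector<int> &cnt) {
  int best = 0;
  for (int k = 1; k < (int)cnt.size(); ++k)
    if (cnt[k] > cnt[best]) best = k; // ties -> lowest class index
  return best + 1;
}

// partial Fisher-Yates draw of m features out of p, using R's RNG
static void sample_features(std::vector<int> &pool, int m) {
  int p = (int)pool.size();
  for (int i = 0; i < m; ++i) {
    int j = i + (int)std::floor(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
  }
}

static int grow_node(const NumericMatrix &X, const IntegerVector &y, int K,
                     std::vector<int> &rows, int depth, int max_features,
                     int min_leaf, std::vector<FlatNode> &nodes) {
  const int n = (int)rows.size();
  std::vector<int> cnt(K, 0);
  for (int i = 0; i < n; ++i) cnt[y[rows[i]] - 1]++;
  int lab = majority_label(cnt);

  int me = (int)nodes.size();
  FlatNode nd;
  nd.feature = 0; nd.threshold = 0.0; nd.left = 0; nd.right = 0;
  nd.label = lab; nd.depth = depth; nd.n = n;
  nodes.push_back(nd);

  bool pure = false;
  for (int k = 0; k < K; ++k) if (cnt[k] == n) pure = true;
  if (pure || n < 2 * min_leaf) return me;

  const int p = X.ncol();
  std::vector<int> pool(p);
  for (int f = 0; f < p; ++f) pool[f] = f;
  int mtry = max_features < p ? max_features : p;
  sample_features(pool, mtry);

  double parent_score = 0.0;
  for (int k = 0; k < K; ++k) parent_score += (double)cnt[k] * cnt[k];
  parent_score /= n;

  int best_f = -1, best_i = -1;
  double best_gain = 1e-10, best_thr = 0.0;
  std::vector<std::pair<double,int> > vals(n);
  std::vector<int> lcnt(K), rcnt(K);

  for (int fi = 0; fi < mtry; ++fi) {
    int f = pool[fi];
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(rows[i], f), y[rows[i]] - 1);
    std::sort(vals.begin(), vals.end());
    if (vals[0].first == vals[n - 1].first) continue;

    std::fill(lcnt.begin(), lcnt.end(), 0);
    for (int k = 0; k < K; ++k) rcnt[k] = cnt[k];
    double lsq = 0.0, rsq = parent_score * n; // running sums of cnt^2
    rsq = 0.0;
    for (int k = 0; k < K; ++k) rsq += (double)cnt[k] * cnt[k];

    for (int i = 0; i < n - 1; ++i) {
      int c = vals[i].second;
      lsq += 2.0 * lcnt[c] + 1.0;
      rsq -= 2.0 * rcnt[c] - 1.0;
      lcnt[c]++; rcnt[c]--;
      if (vals[i + 1].first <= vals[i].first) continue;
      int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double gain = lsq / nl + rsq / nr - parent_score;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        best_i = i;
      }
    }
  }
  if (best_f < 0) return me; // no impurity-reducing split among candidates

  std::vector<int> lrows, rrows;
  lrows.reserve(n); rrows.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (X(rows[i], best_f) <= best_thr) lrows.push_back(rows[i]);
    else rrows.push_back(rows[i]);
  }
  if (lrows.empty() || rrows.empty()) return me; // numeric degeneracy guard

  nodes[me].feature = best_f + 1;
  nodes[me].threshold = best_thr;
  int li = grow_node(X, y, K, lrows, depth + 1, max_features, min_leaf, nodes);
  nodes[me].left = li + 1;
  int ri = grow_node(X, y, K, rrows, depth + 1, max_features, min_leaf, nodes);
  nodes[me].right = ri + 1;
  (void)best_i;
  return me;
}

// [[Rcpp::export]]
NumericMatrix grow_tree_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                            IntegerVector idx, int max_features, int min_leaf) {
  std::vector<int> rows(idx.size());
  for (int i = 0; i < idx.size(); ++i) rows[i] = idx[i] - 1;
  std::vector<FlatNode> nodes;
  nodes.reserve(2 * rows.size());
  grow_node(X, y, n_classes, rows, 1, max_features, min_leaf, nodes);

  NumericMatrix out((int)nodes.size(), 7);
  for (int i = 0; i < (int)nodes.size(); ++i) {
    out(i, 0) = nodes[i].feature;
    out(i, 1) = nodes[i].threshold;
    out(i, 2) = nodes[i].left;
    out(i, 3) = nodes[i].right;
    out(i, 4) = nodes[i].label;
    out(i, 5) = nodes[i].depth;
    out(i, 6) = nodes[i].n;
  }
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "label", "depth", "n");
  return out;
}

static int tree_predict_one(const NumericMatrix &tr, const NumericMatrix &X,
                            int row) {
  int node = 0;
  while (tr(node, 0) > 0) {
    int f = (int)tr(node, 0) - 1;
    node = (X(row, f) <= tr(node, 1)) ? (int)tr(node, 2) - 1
                                      : (int)tr(node, 3) - 1;
  }
  return (int)tr(node, 4);
}

// [[Rcpp::export]]
IntegerVector predict_tree_cpp(NumericMatrix tree, NumericMatrix X) {
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tree_predict_one(tree, X, i);
  return out;
}

// [[Rcpp::export]]
IntegerMatrix forest_votes_cpp(List trees, NumericMatrix X, int n_classes) {
  int n = X.nrow(), T = trees.size();
  IntegerMatrix votes(n, n_classes);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tr = trees[t];
    for (int i = 0; i < n; ++i) {
      int lab = tree_predict_one(tr, X, i);
      votes(i, lab - 1)++;
    }
  }
  return votes;
}
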