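#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

// Bagged CART classification ensemble: per-tree bootstrap of a fixed size,
// sqrt(p)-style random candidate-feature subset drawn anew at EVERY split,
// Gini impurity, nodes grown to purity (or until no valid split), majority
// vote at predict time with ties broken toward the smallest class id.
// Seeded with std::mt19937 so results are identical across platforms.

struct TreeBuf {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;  // child node ids
  std::vector<int> pred;         // majority class at node (leaf prediction)
};

static int majority_class(const std::vector<int>& counts) {
  int best = 0;
  for (size_t c = 1; c < counts.size(); ++c)
    if (counts[c] > counts[best]) best = (int)c;
  return best;
}

static int grow_node(TreeBuf& T, const NumericMatrix& X, const IntegerVector& y,
                     std::vector<int>& idx, int lo, int hi, int n_class,
                     int mtry, std::mt19937& rng) {
  const int n = hi - lo;
  std::vector<int> counts(n_class, 0);
  for (int i = lo; i < hi; ++i) counts[y[idx[i]]]++;
  const int node_id = (int)T.feature.size();
  T.feature.push_back(-1); T.threshold.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1);
  T.pred.push_back(majority_class(counts));

  int n_present = 0;
  for (int c = 0; c < n_class; ++c) if (counts[c] > 0) ++n_present;
  if (n_present <= 1 || n < 2) return node_id;  // pure or singleton

  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  // partial Fisher-Yates: first mtry entries are the candidate features
  for (int j = 0; j < mtry && j < p; ++j) {
    std::uniform_int_distribution<int> U(j, p - 1);
    std::swap(feats[j], feats[U(rng)]);
  }

  double best_gini = R_PosInf, best_thr = 0.0;
  int best_f = -1;
  std::vector<std::pair<double,int>> vals(n);
  std::vector<int> cl(n_class), cr(n_class);

  for (int jj = 0; jj < mtry && jj < p; ++jj) {
    const int f = feats[jj];
    for (int i = 0; i < n; ++i)
      vals[i] = {X(idx[lo + i], f), y[idx[lo + i]]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;  // constant feature
    std::fill(cl.begin(), cl.end(), 0);
    cr = counts;
    for (int i = 0; i < n - 1; ++i) {
      const int c = vals[i].second;
      cl[c]++; cr[c]--;
      if (vals[i].first == vals[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl;
      double gl = 1.0, gr = 1.0;
      for (int k = 0; k < n_class; ++k) {
        const double pl = (double)cl[k] / nl, pr = (double)cr[k] / nr;
        gl -= pl * pl; gr -= pr * pr;
      }
      const double g = (nl * gl + nr * gr) / n;
      if (g < best_gini) {
        best_gini = g; best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return node_id;  // all candidates constant: leaf

  // partition idx[lo:hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node_id;  // numerically degenerate

  T.feature[node_id] = best_f;
  T.threshold[node_id] = best_thr;
  const int l = grow_node(T, X, y, idx, lo, mid, n_class, mtry, rng);
  const int r = grow_node(T, X, y, idx, mid, hi, n_class, mtry, rng);
  T.left[node_id] = l; T.right[node_id] = r;
  return node_id;
}

// [[Rcpp::export(name = ".train_forest_cpp")]]
List train_forest_cpp(NumericMatrix X, IntegerVector y, int n_class,
                      int n_trees, int mtry, int sample_size, int seed) {
  const int n = X.nrow();
  if (n < 1) stop("empty training matrix");
  std::mt19937 rng((uint32_t)seed);
  List trees(n_trees);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int tix = 0; tix < n_trees; ++tix) {
    std::vector<int> idx(sample_size);
    for (int i = 0; i < sample_size; ++i) idx[i] = boot(rng);
    TreeBuf T;
    grow_node(T, X, y, idx, 0, sample_size, n_class, mtry, rng);
    trees[tix] = List::create(
      _["feature"] = wrap(T.feature), _["threshold"] = wrap(T.threshold),
      _["left"] = wrap(T.left), _["right"] = wrap(T.right),
      _["pred"] = wrap(T.pred));
  }
  return trees;
}

// [[Rcpp::export(name = ".predict_forest_cpp")]]
IntegerMatrix predict_forest_cpp(List trees, NumericMatrix X, int n_class) {
  const int n = X.nrow(), n_trees = trees.size();
  IntegerMatrix votes(n, n_class);
  for (int tix = 0; tix < n_trees; ++tix) {
    List T = trees[tix];
    IntegerVector feature = T["feature"], left = T["left"],
                  right = T["right"], pred = T["pred"];
    NumericVector threshold = T["threshold"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      votes(i, pred[node])++;
    }
  }
  return votes;  // caller takes arg-max with smallest-id tie break
}
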