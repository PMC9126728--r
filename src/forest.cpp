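// From-scratch random forest core: CART trees grown on Gini impurity,
// bootstrap bagging, per-node (or per-tree) uniform feature subsampling.
// All randomness comes from R's RNG stream so a single set.seed() on the R
// side makes training a pure function of the seed. RNG consumption order is
// fixed: per tree, the bootstrap draw first (then the tree pool in per-tree
// mode), then per-node candidate subsets in preorder (left subtree before
// right).
#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

static double gini_cnt(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double s = 0.0;
  for (size_t c = 0; c < cnt.size(); ++c) {
    double p = (double)cnt[c] / n;
    s += p * p;
  }
  return 1.0 - s;
}

struct SplitResult {
  int feature;        // 0-based column
  double threshold;   // left branch: x < threshold
  double decrease;    // weighted Gini decrease
  bool found;
};

// Exhaustive search over candidate features and midpoints between
// consecutive distinct sorted values. Ties in decrease break to the lowest
// feature index, then the lowest threshold. Only strictly positive decreases
// qualify.
static SplitResult best_split_impl(const NumericMatrix& x,
                                   const IntegerVector& y,
                                   const std::vector<int>& idx,
                                   const std::vector<int>& cand,
                                   int K, int min_leaf) {
  int n = (int)idx.size();
  std::vector<int> total(K, 0);
  for (int i : idx) total[y[i]]++;
  double g0 = gini_cnt(total, n);
  SplitResult best = { -1, 0.0, 0.0, false };
  std::vector<std::pair<double, int> > vals(n);
  std::vector<int> lc(K), rc(K);
  for (int f : cand) {
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(x(idx[i], f), y[idx[i]]);
    std::sort(vals.begin(), vals.end());
    std::fill(lc.begin(), lc.end(), 0);
    rc = total;
    for (int i = 0; i < n - 1; ++i) {
      lc[vals[i].second]++;
      rc[vals[i].second]--;
      if (vals[i].first < vals[i + 1].first) {
        int nl = i + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double thr = 0.5 * (vals[i].first + vals[i + 1].first);
        double dec = g0 - ((double)nl / n) * gini_cnt(lc, nl)
                        - ((double)nr / n) * gini_cnt(rc, nr);
        if (dec <= 0) continue;
        bool better = !best.found || dec > best.decrease ||
          (dec == best.decrease &&
           (f < best.feature ||
            (f == best.feature && thr < best.threshold)));
        if (better) {
          best.feature = f; best.threshold = thr;
          best.decrease = dec; best.found = true;
        }
      }
    }
  }
  return best;
}

// m distinct features from 0..p-1, partial Fisher-Yates on R's RNG
static std::vector<int> sample_features(int p, int m) {
  std::vector<int> pool(p);
  std::iota(pool.begin(), pool.end(), 0);
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
  }
  pool.resize(m);
  return pool;
}

struct Tree {
  std::vector<int> feature, left, right;
  std::vector<double> threshold;
  std::vector<std::vector<int> > counts;
};

static int grow(const NumericMatrix& x, const IntegerVector& y, Tree& tr,
                const std::vector<int>& idx, int depth, int K, int mtry,
                int max_depth, int min_leaf, bool per_tree,
                const std::vector<int>& tree_pool) {
  int id = (int)tr.feature.size();
  tr.feature.push_back(-1);
  tr.threshold.push_back(NA_REAL);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  int n = (int)idx.size();
  std::vector<int> cnt(K, 0);
  for (int i : idx) cnt[y[i]]++;
  tr.counts.push_back(cnt);

  int n_classes_present = 0;
  for (int c : cnt) if (c > 0) n_classes_present++;
  if (n_classes_present <= 1 || n < 2 || n < 2 * min_leaf ||
      (max_depth >= 0 && depth >= max_depth))
    return id;

  std::vector<int> cand =
    per_tree ? tree_pool : sample_features(x.ncol(), mtry);
  SplitResult s = best_split_impl(x, y, idx, cand, K, min_leaf);
  if (!s.found) return id;

  std::vector<int> li, ri;
  for (int i : idx)
    (x(i, s.feature) < s.threshold ? li : ri).push_back(i);
  tr.feature[id] = s.feature;
  tr.threshold[id] = s.threshold;
  tr.left[id] = grow(x, y, tr, li, depth + 1, K, mtry, max_depth, min_leaf,
                     per_tree, tree_pool);
  tr.right[id] = grow(x, y, tr, ri, depth + 1, K, mtry, max_depth, min_leaf,
                      per_tree, tree_pool);
  return id;
}

// [[Rcpp::export(rng = false)]]
List cpp_best_split(NumericMatrix x, IntegerVector y, IntegerVector cand,
                    int n_classes, int min_leaf) {
  std::vector<int> idx(x.nrow());
  std::iota(idx.begin(), idx.end(), 0);
  std::vector<int> cd(cand.begin(), cand.end());
  SplitResult s = best_split_impl(x, y, idx, cd, n_classes, min_leaf);
  return List::create(_["found"] = s.found, _["feature"] = s.feature,
                      _["threshold"] = s.threshold,
                      _["decrease"] = s.decrease);
}

// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix x, IntegerVector y, int n_classes,
                    int n_trees, int mtry, int max_depth, int min_leaf,
                    bool bootstrap, bool per_tree) {
  int N = x.nrow();
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(N);
    if (bootstrap) {
      for (int i = 0; i < N; ++i) {
        int j = (int)(unif_rand() * N);
        if (j >= N) j = N - 1;
        idx[i] = j;
      }
    } else {
      std::iota(idx.begin(), idx.end(), 0);
    }
    std::vector<int> pool;
    if (per_tree) pool = sample_features(x.ncol(), mtry);
    Tree tr;
    grow(x, y, tr, idx, 0, n_classes, mtry, max_depth, min_leaf, per_tree,
         pool);
    int nn = (int)tr.feature.size();
    IntegerMatrix cnts(nn, n_classes);
    for (int i = 0; i < nn; ++i)
      for (int c = 0; c < n_classes; ++c)
        cnts(i, c) = tr.counts[i][c];
    IntegerVector boot(idx.begin(), idx.end());
    trees[t] = List::create(
      _["feature"] = IntegerVector(tr.feature.begin(), tr.feature.end()),
      _["threshold"] = NumericVector(tr.threshold.begin(), tr.threshold.end()),
      _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
      _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
      _["counts"] = cnts,
      _["bootstrap"] = boot);
  }
  return trees;
}

// Per-sample class votes: each tree votes its leaf's majority class (leaf
// ties break to the lowest class index, i.e. the fixed class order).
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_predict_votes(List trees, NumericMatrix newx,
                                int n_classes) {
  int n = newx.nrow();
  IntegerMatrix votes(n, n_classes);
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector thr = tr["threshold"];
    IntegerMatrix cnts = tr["counts"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = newx(i, feature[node]) < thr[node] ? left[node] : right[node];
      int best = 0, bc = cnts(node, 0);
      for (int c = 1; c < n_classes; ++c)
        if (cnts(node, c) > bc) { bc = cnts(node, c); best = c; }
      votes(i, best)++;
    }
  }
  return votes;
}
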