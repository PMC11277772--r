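// Gini-split classification forest with recorded bootstrap bags.
//
// All randomness goes through R's RNG (unif_rand) so forests are fully
// reproducible under set.seed() from the R side.  Trees are grown unpruned
// until node purity or the minimum node size, splits chosen by least
// weighted child Gini with deterministic tie-breaking (lowest feature
// index, then lowest threshold).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;      // split feature (1-based), -1 for leaf
  std::vector<double> threshold; // x <= threshold goes left
  std::vector<int> left, right;  // child node ids, -1 for leaf
  std::vector<int> pred;         // majority class (1..c) at node
  std::vector<int> nobs;         // in-bag samples reaching node
  std::vector<double> gini;      // node Gini impurity
};

int majority_class(const std::vector<int>& counts) {
  int best = 0;
  for (size_t i = 1; i < counts.size(); ++i)
    if (counts[i] > counts[best]) best = (int)i;
  return best + 1; // smallest index wins ties via strict >
}

double gini_from_counts(const std::vector<int>& counts, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (size_t i = 0; i < counts.size(); ++i) {
    double p = (double)counts[i] / n;
    g -= p * p;
  }
  return g;
}

// draw `m` distinct values from pool (partial Fisher-Yates), ascending order
std::vector<int> draw_distinct(std::vector<int> pool, int m) {
  int n = (int)pool.size();
  if (m > n) m = n;
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
  }
  pool.resize(m);
  std::sort(pool.begin(), pool.end());
  return pool;
}

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y; // 1..c
  int nclass, mtry, nmin;
  std::vector<int> groupS, groupW; // 0-based column ids; empty => plain draws
  // full-column sort orders, shared across the trees of one forest; at
  // large nodes the split scan walks these instead of re-sorting
  const std::vector<std::vector<int>>* order;
  std::vector<int> node_cnt; // scratch: per-row multiplicity in the node
  TreeNodes tree;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int nclass_,
          int mtry_, int nmin_, const std::vector<int>& gS,
          const std::vector<int>& gW,
          const std::vector<std::vector<int>>* order_)
      : X(X_), y(y_), nclass(nclass_), mtry(mtry_), nmin(nmin_),
        groupS(gS), groupW(gW), order(order_), node_cnt(X_.nrow(), 0) {}

  std::vector<int> candidates() {
    if (groupS.empty()) {
      std::vector<int> pool(X.ncol());
      for (int j = 0; j < X.ncol(); ++j) pool[j] = j;
      return draw_distinct(pool, mtry);
    }
    // group-stratified: ceil(mtry/2) from Ys, floor(mtry/2) from Yw,
    // always at least one from Ys
    int ns = (mtry + 1) / 2, nw = mtry / 2;
    if (ns < 1) ns = 1;
    std::vector<int> cand = draw_distinct(groupS, ns);
    std::vector<int> cw = draw_distinct(groupW, nw);
    cand.insert(cand.end(), cw.begin(), cw.end());
    std::sort(cand.begin(), cand.end());
    return cand;
  }

  int grow(std::vector<int>& idx) {
    int node = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);

    int n = (int)idx.size();
    std::vector<int> counts(nclass, 0);
    for (int i : idx) counts[y[i] - 1]++;
    tree.pred.push_back(majority_class(counts));
    tree.nobs.push_back(n);

    double parent_gini = gini_from_counts(counts, n);
    tree.gini.push_back(parent_gini);
    if (n < 2 * nmin || n < 2 || parent_gini <= 0.0) return node;

    std::vector<int> cand = candidates();

    int best_feat = -1;
    double best_thr = 0.0, best_score = parent_gini - 1e-12;
    // candidates are ascending, scan thresholds ascending, strict < :
    // ties resolve to lowest feature index then lowest threshold
    const bool use_order = order != nullptr && n >= 32;
    if (use_order)
      for (int i : idx) node_cnt[i]++;

    std::vector<std::pair<double, int>> vals;
    std::vector<int> lc(nclass), rc(nclass);
    for (int f : cand) {
      std::fill(lc.begin(), lc.end(), 0);
      rc = counts;
      if (use_order) {
        // walk the presorted full column, skipping rows outside the node
        const std::vector<int>& ord = (*order)[f];
        double prev = 0.0;
        bool started = false;
        int nl = 0;
        for (int r : ord) {
          int c = node_cnt[r];
          if (c == 0) continue;
          double v = X(r, f);
          if (started && v != prev) {
            int nr = n - nl;
            if (nl >= nmin && nr >= nmin) {
              double score = (nl * gini_from_counts(lc, nl) +
                              nr * gini_from_counts(rc, nr)) / n;
              if (score < best_score) {
                best_score = score;
                best_feat = f;
                best_thr = 0.5 * (prev + v);
              }
            }
          }
          lc[y[r] - 1] += c;
          rc[y[r] - 1] -= c;
          nl += c;
          prev = v;
          started = true;
        }
      } else {
        vals.resize(n);
        for (int i = 0; i < n; ++i)
          vals[i] = std::make_pair(X(idx[i], f), y[idx[i]] - 1);
        std::sort(vals.begin(), vals.end());
        std::fill(lc.begin(), lc.end(), 0);
        rc = counts;
        for (int i = 0; i < n - 1; ++i) {
          lc[vals[i].second]++;
          rc[vals[i].second]--;
          if (vals[i].first == vals[i + 1].first) continue;
          int nl = i + 1, nr = n - nl;
          if (nl < nmin || nr < nmin) continue;
          double score = (nl * gini_from_counts(lc, nl) +
                          nr * gini_from_counts(rc, nr)) / n;
          if (score < best_score) {
            best_score = score;
            best_feat = f;
            best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          }
        }
      }
    }
    if (use_order)
      for (int i : idx) node_cnt[i] = 0;
    if (best_feat < 0) return node;

    std::vector<int> li, ri;
    for (int i : idx)
      (X(i, best_feat) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return node; // degenerate, keep leaf

    tree.feature[node] = best_feat + 1;
    tree.threshold[node] = best_thr;
    int l = grow(li);
    int r = grow(ri);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

int predict_one(const IntegerVector& feature, const NumericVector& threshold,
                const IntegerVector& left, const IntegerVector& right,
                const IntegerVector& pred, const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] > 0) {
    node = (X(row, feature[node] - 1) <= threshold[node]) ? left[node]
                                                          : right[node];
  }
  return pred[node];
}

} // namespace

// [[Rcpp::export(name = ".rf_build_cpp")]]
List rf_build_cpp(NumericMatrix X, IntegerVector y, int nclass, int K,
                  int mtry, int nmin, IntegerVector group_s,
                  IntegerVector group_w) {
  int N = X.nrow();
  std::vector<int> gS(group_s.begin(), group_s.end());
  std::vector<int> gW(group_w.begin(), group_w.end());
  for (int& v : gS) v -= 1; // to 0-based
  for (int& v : gW) v -= 1;

  // one full sort per column, shared by all trees of the forest
  std::vector<std::vector<int>> order(X.ncol());
  for (int j = 0; j < X.ncol(); ++j) {
    order[j].resize(N);
    for (int i = 0; i < N; ++i) order[j][i] = i;
    const int col = j;
    std::stable_sort(order[j].begin(), order[j].end(),
                     [&X, col](int a, int b) { return X(a, col) < X(b, col); });
  }

  List trees(K);
  IntegerMatrix inbag(N, K);
  for (int k = 0; k < K; ++k) {
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) {
      int j = (int)(unif_rand() * N);
      if (j >= N) j = N - 1;
      idx[i] = j;
      inbag(j, k)++;
    }
    Builder b(X, y, nclass, mtry, nmin, gS, gW, &order);
    b.grow(idx);
    trees[k] = List::create(
        Named("feature") = wrap(b.tree.feature),
        Named("threshold") = wrap(b.tree.threshold),
        Named("left") = wrap(b.tree.left),
        Named("right") = wrap(b.tree.right),
        Named("pred") = wrap(b.tree.pred),
        Named("nobs") = wrap(b.tree.nobs),
        Named("gini") = wrap(b.tree.gini));
  }
  return List::create(Named("trees") = trees, Named("inbag") = inbag);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
IntegerMatrix rf_predict_cpp(List trees, NumericMatrix X) {
  int K = trees.size(), N = X.nrow();
  IntegerMatrix out(N, K);
  for (int k = 0; k < K; ++k) {
    List t = trees[k];
    IntegerVector feature = t["feature"];
    NumericVector threshold = t["threshold"];
    IntegerVector left = t["left"], right = t["right"], pred = t["pred"];
    for (int i = 0; i < N; ++i)
      out(i, k) = predict_one(feature, threshold, left, right, pred, X, i);
  }
  return out;
}

// Per-feature permutation importance: for each tree, the increase in that
// tree's out-of-bag error when the feature's OOB values are permuted,
// averaged over trees.
// [[Rcpp::export(name = ".rf_perm_importance_cpp")]]
NumericVector rf_perm_importance_cpp(List trees, IntegerMatrix inbag,
                                     NumericMatrix X, IntegerVector y) {
  int K = trees.size(), N = X.nrow(), M = X.ncol();
  NumericVector imp(M);
  NumericMatrix Xp(clone(X));
  int used_trees = 0;
  for (int k = 0; k < K; ++k) {
    List t = trees[k];
    IntegerVector feature = t["feature"];
    NumericVector threshold = t["threshold"];
    IntegerVector left = t["left"], right = t["right"], pred = t["pred"];

    std::vector<int> oob;
    for (int i = 0; i < N; ++i)
      if (inbag(i, k) == 0) oob.push_back(i);
    int no = (int)oob.size();
    if (no < 2) continue;
    used_trees++;

    int base_err = 0;
    for (int i : oob)
      if (predict_one(feature, threshold, left, right, pred, X, i) != y[i])
        base_err++;
    double base = (double)base_err / no;

    // which features does this tree actually use?
    std::vector<bool> used(M, false);
    for (int nd = 0; nd < feature.size(); ++nd)
      if (feature[nd] > 0) used[feature[nd] - 1] = true;

    std::vector<int> perm(no);
    for (int j = 0; j < M; ++j) {
      if (!used[j]) continue; // permuting an unused feature changes nothing
      for (int i = 0; i < no; ++i) perm[i] = i;
      for (int i = no - 1; i > 0; --i) {
        int r = (int)(unif_rand() * (i + 1));
        if (r > i) r = i;
        std::swap(perm[i], perm[r]);
      }
      for (int i = 0; i < no; ++i) Xp(oob[i], j) = X(oob[perm[i]], j);
      int err = 0;
      for (int i : oob)
        if (predict_one(feature, threshold, left, right, pred, Xp, i) != y[i])
          err++;
      imp[j] += (double)err / no - base;
      for (int i = 0; i < no; ++i) Xp(oob[i], j) = X(oob[i], j);
    }
  }
  if (used_trees > 0)
    for (int j = 0; j < M; ++j) imp[j] /= used_trees;
  return imp;
}

// Exposed for testing the group-stratified candidate draw.
// [[Rcpp::export(name = ".rf_draw_candidates_cpp")]]
IntegerVector rf_draw_candidates_cpp(int M, int mtry, IntegerVector group_s,
                                     IntegerVector group_w) {
  std::vector<int> gS(group_s.begin(), group_s.end());
  std::vector<int> gW(group_w.begin(), group_w.end());
  for (int& v : gS) v -= 1;
  for (int& v : gW) v -= 1;
  NumericMatrix dummy(1, M);
  IntegerVector ydummy(1, 1);
  Builder b(dummy, ydummy, 1, mtry, 1, gS, gW, nullptr);
  std::vector<int> cand = b.candidates();
  for (int& v : cand) v += 1;
  return wrap(cand);
}
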