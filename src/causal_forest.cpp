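// Honest double-sample causal trees on orthogonalized (residualized) data.
//
// Each tree draws a subsample (rows, or whole clusters when cluster ids are
// supplied), partitions it into a split half and an estimate half, chooses
// axis-aligned splits on the split half by maximizing between-child
// heterogeneity of the residual-on-residual effect, and populates leaf
// effects from the estimate half only.  All randomness comes from R's RNG,
// so determinism is governed by set.seed() on the calling side.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

// draw k of 0..(n-1) without replacement (partial Fisher-Yates, R RNG)
std::vector<int> sample_k_of_n(int n, int k) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + static_cast<int>(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
  }
  pool.resize(k);
  return pool;
}

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // x <= threshold goes left
  std::vector<int> left, right, parent;
  std::vector<double> value;     // leaf (and internal fallback) effect
};

struct Builder {
  const NumericMatrix& X;
  const NumericVector& yres;
  const NumericVector& tres;
  const IntegerVector& treat;
  int min_leaf;
  int max_depth;   // <0 means unlimited
  bool regression; // plain regression tree: no per-arm constraints
  Tree tree;

  Builder(const NumericMatrix& X_, const NumericVector& y_,
          const NumericVector& t_, const IntegerVector& w_,
          int min_leaf_, int max_depth_, bool regression_)
      : X(X_), yres(y_), tres(t_), treat(w_), min_leaf(min_leaf_),
        max_depth(max_depth_), regression(regression_) {}

  int new_node(int parent_id) {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.parent.push_back(parent_id);
    tree.value.push_back(0.0);
    return static_cast<int>(tree.feature.size()) - 1;
  }

  // Grow a node from per-feature presorted row orders (all p vectors hold
  // the same row set, each sorted by its feature).  Presorting once at the
  // root and partitioning stably at each split keeps every scan linear.
  int grow(std::vector<std::vector<int>>& orders, int depth, int parent_id) {
    int id = new_node(parent_id);
    const int p = static_cast<int>(orders.size());
    const int n = static_cast<int>(orders[0].size());

    double totA = 0.0, totS = 0.0;
    int totT = 0;
    for (int r : orders[0]) {
      totA += tres[r] * tres[r];
      totS += tres[r] * yres[r];
      totT += treat[r];
    }
    const int totC = n - totT;
    const bool arms_ok = regression || (totT > 0 && totC > 0);
    const bool can_split =
        n >= 2 * min_leaf && arms_ok && totA > 1e-12 &&
        (max_depth < 0 || depth < max_depth);
    if (!can_split) return id;

    const double parent_score = totS * totS / totA;
    double best_gain = parent_score + 1e-10;
    int best_feat = -1;
    double best_thr = 0.0;

    // ascending feature scan + strictly-better acceptance gives the
    // deterministic tie-break: lowest feature index, lowest threshold
    for (int j = 0; j < p; ++j) {
      const std::vector<int>& order = orders[j];
      double cumA = 0.0, cumS = 0.0;
      int cnt = 0, ct = 0;
      for (int k = 0; k < n - 1; ++k) {
        const int r = order[k];
        cumA += tres[r] * tres[r];
        cumS += tres[r] * yres[r];
        ++cnt;
        ct += treat[r];
        if (X(r, j) == X(order[k + 1], j)) continue; // no cut between ties
        const int nl = cnt, nr = n - cnt;
        if (nl < min_leaf || nr < min_leaf) continue;
        const int lt = ct, lc = cnt - ct, rt = totT - ct, rc = nr - rt;
        if (!regression && (lt == 0 || lc == 0 || rt == 0 || rc == 0))
          continue;
        const double rA = totA - cumA, rS = totS - cumS;
        if (cumA <= 1e-12 || rA <= 1e-12) continue;
        const double gain = cumS * cumS / cumA + rS * rS / rA;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = j;
          best_thr = 0.5 * (X(r, j) + X(order[k + 1], j));
        }
      }
    }
    if (best_feat < 0) return id;

    // stable partition of every feature order preserves sortedness
    std::vector<std::vector<int>> lorders(p), rorders(p);
    for (int j = 0; j < p; ++j) {
      lorders[j].reserve(n);
      rorders[j].reserve(n);
      for (int r : orders[j])
        (X(r, best_feat) <= best_thr ? lorders[j] : rorders[j]).push_back(r);
    }
    if (static_cast<int>(lorders[0].size()) < min_leaf ||
        static_cast<int>(rorders[0].size()) < min_leaf)
      return id; // numeric ties at boundary; keep as leaf
    orders.clear();
    orders.shrink_to_fit();

    tree.feature[id] = best_feat;
    tree.threshold[id] = best_thr;
    const int l = grow(lorders, depth + 1, id);
    tree.left[id] = l;
    const int r2 = grow(rorders, depth + 1, id);
    tree.right[id] = r2;
    return id;
  }

  // entry point: build presorted per-feature orders, then grow
  int grow_root(const std::vector<int>& rows) {
    const int p = X.ncol();
    std::vector<std::vector<int>> orders(p);
    for (int j = 0; j < p; ++j) {
      orders[j] = rows;
      std::sort(orders[j].begin(), orders[j].end(), [&](int a, int b) {
        double xa = X(a, j), xb = X(b, j);
        if (xa != xb) return xa < xb;
        return a < b;
      });
    }
    return grow(orders, 0, -1);
  }
};

// flat view of one fitted tree for fast repeated descents
struct TreeView {
  IntegerVector feature, left, right;
  NumericVector threshold, value;
  explicit TreeView(const List& tr)
      : feature(tr["feature"]), left(tr["left"]), right(tr["right"]),
        threshold(tr["threshold"]), value(tr["value"]) {}
  double predict(const NumericMatrix& X, int row) const {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(row, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
    }
    return value[node];
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_cf_fit(NumericMatrix X, NumericVector yres, NumericVector tres,
                IntegerVector treat, IntegerVector cluster, int n_trees,
                double subsample_fraction, double honesty_fraction,
                int min_leaf, int max_depth, bool regression) {
  RNGScope scope;
  const int n = X.nrow();
  const bool clustered = cluster.size() == n;

  // cluster index -> member rows
  std::vector<std::vector<int>> members;
  int n_clusters = 0;
  if (clustered) {
    for (int i = 0; i < n; ++i) n_clusters = std::max(n_clusters, cluster[i]);
    members.assign(n_clusters, {});
    for (int i = 0; i < n; ++i) members[cluster[i] - 1].push_back(i);
  }

  List trees(n_trees);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> split_rows, est_rows, inbag;
    if (clustered) {
      int kc = std::max(2, static_cast<int>(
                               std::ceil(subsample_fraction * n_clusters)));
      kc = std::min(kc, n_clusters);
      std::vector<int> cl = sample_k_of_n(n_clusters, kc);
      // honesty at the cluster level: whole clusters go to one half
      int ks = std::max(1, static_cast<int>(honesty_fraction * kc));
      if (ks >= kc) ks = kc - 1;
      for (int ci = 0; ci < kc; ++ci) {
        auto& dest = (ci < ks) ? split_rows : est_rows;
        for (int r : members[cl[ci]]) {
          dest.push_back(r);
          inbag.push_back(r);
        }
      }
    } else {
      int k = std::max(4, static_cast<int>(subsample_fraction * n));
      k = std::min(k, n);
      inbag = sample_k_of_n(n, k);
      int ks = std::max(2, static_cast<int>(honesty_fraction * k));
      if (ks >= k) ks = k - 1;
      split_rows.assign(inbag.begin(), inbag.begin() + ks);
      est_rows.assign(inbag.begin() + ks, inbag.end());
    }

    Builder bld(X, yres, tres, treat, min_leaf, max_depth, regression);
    bld.grow_root(split_rows);
    Tree& tr = bld.tree;
    const int n_nodes = static_cast<int>(tr.feature.size());

    // estimate-half statistics accumulated along each row's path
    std::vector<double> A(n_nodes, 0.0), S(n_nodes, 0.0);
    std::vector<int> nT(n_nodes, 0), nC(n_nodes, 0);
    for (int r : est_rows) {
      int node = 0;
      while (true) {
        A[node] += tres[r] * tres[r];
        S[node] += tres[r] * yres[r];
        if (treat[r]) ++nT[node]; else ++nC[node];
        if (tr.feature[node] < 0) break;
        node = (X(r, tr.feature[node]) <= tr.threshold[node]) ? tr.left[node]
                                                              : tr.right[node];
      }
    }
    // leaf effect: nearest ancestor (incl. self) with both arms and signal
    // (regression mode only needs estimate-half mass in the node)
    for (int v = 0; v < n_nodes; ++v) {
      int node = v;
      while (node >= 0 &&
             !((regression || (nT[node] > 0 && nC[node] > 0)) &&
               A[node] > 1e-12))
        node = tr.parent[node];
      tr.value[v] = (node >= 0) ? S[node] / A[node] : 0.0;
    }

    trees[b] = List::create(
        _["feature"] = wrap(tr.feature), _["threshold"] = wrap(tr.threshold),
        _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
        _["parent"] = wrap(tr.parent), _["value"] = wrap(tr.value),
        _["split_rows"] = wrap(split_rows), _["est_rows"] = wrap(est_rows),
        _["inbag"] = wrap(inbag));
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector cpp_cf_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n, 0.0);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    TreeView tv(tr);
    for (int i = 0; i < n; ++i) out[i] += tv.predict(X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}

// out-of-bag prediction over the training matrix: each row is predicted
// only by trees whose subsample excluded it
// [[Rcpp::export]]
NumericVector cpp_cf_predict_oob(List trees, NumericMatrix X) {
  const int n = X.nrow(), B = trees.size();
  std::vector<double> sum(n, 0.0), all_sum(n, 0.0);
  std::vector<int> cnt(n, 0);
  std::vector<char> inbag(n);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    TreeView tv(tr);
    IntegerVector bag = tr["inbag"];
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < bag.size(); ++i) inbag[bag[i]] = 1;
    for (int i = 0; i < n; ++i) {
      const double v = tv.predict(X, i);
      all_sum[i] += v;
      if (!inbag[i]) {
        sum[i] += v;
        ++cnt[i];
      }
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cnt[i] > 0 ? sum[i] / cnt[i] : all_sum[i] / B;
  return out;
}
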