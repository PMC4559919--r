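#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Park-Miller MINSTD linear congruential generator.  Chosen over R's RNG on
// purpose: the draw sequence is trivially replayable in interpreted code
// (all intermediates stay below 2^53, exact in doubles), forest fits do not
// disturb or depend on R's RNG state, and per-feature seeding makes results
// invariant to gene processing order and parallel scheduling.
struct MinStd {
  double s;
  // a - floor(a/m)*m; exact for the magnitudes used here (< 2^53)
  static double dmod(double a, double m) { return a - std::floor(a / m) * m; }
  explicit MinStd(double seed) {
    s = dmod(seed, 2147483647.0);
    if (s <= 0.0) s += 2147483646.0;
  }
  double unif() {
    s = dmod(16807.0 * s, 2147483647.0);
    return s / 2147483647.0;
  }
  int upto(int k) {  // integer in [0, k)
    int v = (int)(unif() * (double)k);
    return v >= k ? k - 1 : v;
  }
};

struct TreeBuild {
  std::vector<int> split_var;   // 1-based predictor index, -1 for leaf
  std::vector<double> split_val;
  std::vector<int> left, right; // 1-based node index, -1 for leaf
  std::vector< std::vector<int> > leaf_samples; // 1-based distinct in-bag ids
};

// Grow one node (preorder, left child first).  samp holds bootstrap draws
// with multiplicity; identical rows always travel together so distinct
// supports of the leaves partition the in-bag support.
static int grow_node(const NumericMatrix& X, const NumericMatrix& Ys,
                     std::vector<int>& samp, int min_node, int mtry,
                     MinStd& rng, TreeBuild& tb) {
  const int nn = (int)samp.size();
  const int p = X.ncol();
  const int nr = Ys.ncol();

  int best_var = -1;
  double best_val = 0.0, best_gain = 0.0;

  if (nn >= 2 * min_node) {
    // node totals per response
    std::vector<double> tot(nr, 0.0);
    for (int i = 0; i < nn; ++i)
      for (int r = 0; r < nr; ++r) tot[r] += Ys(samp[i], r);
    double base = 0.0;
    for (int r = 0; r < nr; ++r) base += tot[r] * tot[r] / nn;

    // sample mtry distinct predictors (partial Fisher-Yates)
    std::vector<int> vars(p);
    for (int j = 0; j < p; ++j) vars[j] = j;
    int m = mtry < p ? mtry : p;
    for (int j = 0; j < m; ++j) {
      int k = j + rng.upto(p - j);
      std::swap(vars[j], vars[k]);
    }

    std::vector<int> ord(nn);
    std::vector<double> cum(nr);
    for (int j = 0; j < m; ++j) {
      const int v = vars[j];
      for (int i = 0; i < nn; ++i) ord[i] = i;
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double xa = X(samp[a], v), xb = X(samp[b], v);
        if (xa != xb) return xa < xb;
        return a < b;  // stable, deterministic
      });
      std::fill(cum.begin(), cum.end(), 0.0);
      for (int i = 0; i < nn - 1; ++i) {
        for (int r = 0; r < nr; ++r) cum[r] += Ys(samp[ord[i]], r);
        double xi = X(samp[ord[i]], v), xj = X(samp[ord[i + 1]], v);
        if (xi == xj) continue;
        int k = i + 1;
        if (k < min_node || nn - k < min_node) continue;
        double g = 0.0;
        for (int r = 0; r < nr; ++r) {
          double L = cum[r], R = tot[r] - L;
          g += L * L / k + R * R / (nn - k);
        }
        g -= base;
        double thr = (xi + xj) / 2.0;
        bool take = false;
        if (g > best_gain) take = true;
        else if (g == best_gain && best_var >= 0) {
          if (v < best_var || (v == best_var && thr < best_val)) take = true;
        }
        if (take) { best_gain = g; best_var = v; best_val = thr; }
      }
    }
    if (best_gain <= 0.0) best_var = -1;  // no variance reduction possible
  }

  int me = (int)tb.split_var.size();
  tb.split_var.push_back(-1);
  tb.split_val.push_back(0.0);
  tb.left.push_back(-1);
  tb.right.push_back(-1);
  tb.leaf_samples.push_back(std::vector<int>());

  if (best_var < 0) {
    // leaf: distinct in-bag support, ascending, 1-based
    std::vector<int> u(samp);
    std::sort(u.begin(), u.end());
    u.erase(std::unique(u.begin(), u.end()), u.end());
    for (size_t i = 0; i < u.size(); ++i) u[i] += 1;
    tb.leaf_samples[me] = u;
    return me;
  }

  std::vector<int> ls, rs;
  for (int i = 0; i < nn; ++i) {
    if (X(samp[i], best_var) <= best_val) ls.push_back(samp[i]);
    else rs.push_back(samp[i]);
  }
  tb.split_var[me] = best_var + 1;
  tb.split_val[me] = best_val;
  int li = grow_node(X, Ys, ls, min_node, mtry, rng, tb);
  tb.left[me] = li + 1;
  int ri = grow_node(X, Ys, rs, min_node, mtry, rng, tb);
  tb.right[me] = ri + 1;
  return me;
}

// [[Rcpp::export]]
List qrf_grow_cpp(NumericMatrix X, NumericMatrix Ys, int ntree, int mtry,
                  int min_node, double seed) {
  const int n = X.nrow();
  MinStd rng(seed);
  List trees(ntree);
  IntegerMatrix inbag(n, ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> samp(n);
    for (int i = 0; i < n; ++i) {
      samp[i] = rng.upto(n);
      inbag(samp[i], t) += 1;
    }
    TreeBuild tb;
    grow_node(X, Ys, samp, min_node, mtry, rng, tb);
    int nn = (int)tb.split_var.size();
    List leaves(nn);
    for (int q = 0; q < nn; ++q) leaves[q] = wrap(tb.leaf_samples[q]);
    trees[t] = List::create(
      Named("split_var") = wrap(tb.split_var),
      Named("split_val") = wrap(tb.split_val),
      Named("left") = wrap(tb.left),
      Named("right") = wrap(tb.right),
      Named("leaf_samples") = leaves);
  }
  return List::create(Named("trees") = trees, Named("inbag") = inbag);
}

// [[Rcpp::export]]
IntegerVector qrf_which_leaf_cpp(IntegerVector split_var,
                                 NumericVector split_val,
                                 IntegerVector left, IntegerVector right,
                                 NumericMatrix Xnew) {
  const int m = Xnew.nrow();
  IntegerVector out(m);
  for (int i = 0; i < m; ++i) {
    int node = 0;
    while (split_var[node] != -1) {
      int v = split_var[node] - 1;
      node = (Xnew(i, v) <= split_val[node] ? left[node] : right[node]) - 1;
    }
    out[i] = node + 1;  // 1-based node id
  }
  return out;
}
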