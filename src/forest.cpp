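// Minimal CART-style tree/forest engine.
//
// One builder serves classification and regression: for a binary 0/1
// response, variance reduction is proportional to Gini-impurity reduction,
// so leaf means are class-1 probabilities and the accumulated split gain is
// the usual impurity-based importance. Gradient boosting reuses the same
// builder on pseudo-residuals. All randomness draws from R's RNG so that
// set.seed() on the R side gives bit-reproducible forests.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;  // -1 => leaf
  std::vector<double> thresh;
  std::vector<int> left, right;
  std::vector<double> value;  // weighted mean of y in node
};

int new_node(TreeNodes &t) {
  t.feature.push_back(-1);
  t.thresh.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.value.push_back(0.0);
  return (int)t.feature.size() - 1;
}

// Sample `m` feature indices without replacement from 0..p-1.
void sample_features(int p, int m, std::vector<int> &out) {
  static thread_local std::vector<int> pool;
  pool.resize(p);
  for (int i = 0; i < p; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

struct Builder {
  const NumericMatrix &X;
  const NumericVector &y;
  const NumericVector &w;
  int mtry, max_depth, min_node;
  bool random_split;  // extra-trees style: one uniform threshold per feature
  TreeNodes tree;
  std::vector<double> importance;

  Builder(const NumericMatrix &X_, const NumericVector &y_,
          const NumericVector &w_, int mtry_, int max_depth_, int min_node_,
          bool random_split_)
      : X(X_), y(y_), w(w_), mtry(mtry_), max_depth(max_depth_),
        min_node(min_node_), random_split(random_split_),
        importance(X_.ncol(), 0.0) {}

  int build(std::vector<int> &idx, int depth) {
    int node = new_node(tree);
    double sw = 0.0, swy = 0.0, swy2 = 0.0;
    for (int i : idx) {
      sw += w[i];
      swy += w[i] * y[i];
      swy2 += w[i] * y[i] * y[i];
    }
    double mean = (sw > 0) ? swy / sw : 0.0;
    tree.value[node] = mean;
    double sse = swy2 - sw * mean * mean;  // weighted SSE in node
    if (depth >= max_depth || (int)idx.size() < 2 * min_node || sse <= 1e-12)
      return node;

    int p = X.ncol();
    int m = std::min(mtry, p);
    std::vector<int> feats;
    sample_features(p, m, feats);

    double best_gain = 1e-12;
    int best_f = -1;
    double best_t = 0.0;

    std::vector<std::pair<double, int> > vals;
    for (int f : feats) {
      if (random_split) {
        double lo = R_PosInf, hi = R_NegInf;
        for (int i : idx) {
          double v = X(i, f);
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
        if (!(hi > lo)) continue;
        double t = lo + unif_rand() * (hi - lo);
        double swl = 0, syl = 0, syl2 = 0;
        int nl = 0;
        for (int i : idx)
          if (X(i, f) <= t) {
            swl += w[i];
            syl += w[i] * y[i];
            syl2 += w[i] * y[i] * y[i];
            ++nl;
          }
        int nr = (int)idx.size() - nl;
        if (nl < min_node || nr < min_node || swl <= 0 || sw - swl <= 0)
          continue;
        double swr = sw - swl, syr = swy - syl, syr2 = swy2 - syl2;
        double sse_l = syl2 - syl * syl / swl;
        double sse_r = syr2 - syr * syr / swr;
        double gain = sse - sse_l - sse_r;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_t = t;
        }
      } else {
        vals.clear();
        for (int i : idx) vals.push_back(std::make_pair(X(i, f), i));
        std::sort(vals.begin(), vals.end());
        double swl = 0, syl = 0, syl2 = 0;
        int n = (int)vals.size();
        for (int k = 0; k < n - 1; ++k) {
          int i = vals[k].second;
          swl += w[i];
          syl += w[i] * y[i];
          syl2 += w[i] * y[i] * y[i];
          if (vals[k + 1].first <= vals[k].first) continue;  // tie
          int nl = k + 1, nr = n - nl;
          if (nl < min_node || nr < min_node) continue;
          double swr = sw - swl;
          if (swl <= 0 || swr <= 0) continue;
          double syr = swy - syl, syr2 = swy2 - syl2;
          double sse_l = syl2 - syl * syl / swl;
          double sse_r = syr2 - syr * syr / swr;
          double gain = sse - sse_l - sse_r;
          if (gain > best_gain) {
            best_gain = gain;
            best_f = f;
            best_t = 0.5 * (vals[k].first + vals[k + 1].first);
          }
        }
      }
    }
    if (best_f < 0) return node;

    std::vector<int> lidx, ridx;
    for (int i : idx)
      (X(i, best_f) <= best_t ? lidx : ridx).push_back(i);
    if (lidx.empty() || ridx.empty()) return node;

    importance[best_f] += best_gain;
    tree.feature[node] = best_f;
    tree.thresh[node] = best_t;
    tree.left[node] = build(lidx, depth + 1);
    tree.right[node] = build(ridx, depth + 1);
    return node;
  }
};

NumericMatrix pack_tree(const TreeNodes &t) {
  int n = (int)t.feature.size();
  NumericMatrix m(n, 5);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = t.feature[i];
    m(i, 1) = t.thresh[i];
    m(i, 2) = t.left[i];
    m(i, 3) = t.right[i];
    m(i, 4) = t.value[i];
  }
  colnames(m) = CharacterVector::create("feature", "thresh", "left", "right",
                                        "value");
  return m;
}

double predict_one(const NumericMatrix &tree, const NumericMatrix &X,
                   int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2)
                                        : (int)tree(node, 3);
  }
  return tree(node, 4);
}

}  // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericVector y, NumericVector w,
                     int ntree, int mtry, int max_depth, int min_node,
                     bool bootstrap, bool random_split,
                     bool oob_importance = false) {
  int n = X.nrow(), p = X.ncol();
  List trees(ntree);
  NumericVector imp(p), oob_imp(p);
  std::vector<int> idx;
  std::vector<bool> inbag(n);
  std::vector<int> oob, perm;
  NumericMatrix Xp;
  for (int t = 0; t < ntree; ++t) {
    idx.clear();
    if (bootstrap) {
      std::fill(inbag.begin(), inbag.end(), false);
      for (int i = 0; i < n; ++i) {
        int j = (int)(unif_rand() * n);
        if (j >= n) j = n - 1;
        idx.push_back(j);
        inbag[j] = true;
      }
    } else {
      for (int i = 0; i < n; ++i) idx.push_back(i);
    }
    Builder b(X, y, w, mtry, max_depth, min_node, random_split);
    b.build(idx, 0);
    NumericMatrix tr = pack_tree(b.tree);
    trees[t] = tr;
    for (int f = 0; f < p; ++f) imp[f] += b.importance[f];

    if (oob_importance && bootstrap) {
      // out-of-bag permutation importance: squared-error increase on OOB
      // rows when one feature is shuffled. Chance correlations that do not
      // generalize out-of-sample earn ~0 here (unlike impurity gains).
      oob.clear();
      for (int i = 0; i < n; ++i)
        if (!inbag[i]) oob.push_back(i);
      int no = (int)oob.size();
      if (no < 2) continue;
      double base = 0.0;
      for (int i : oob) {
        double e = y[i] - predict_one(tr, X, i);
        base += e * e;
      }
      for (int f = 0; f < p; ++f) {
        if (b.importance[f] <= 0) continue;  // feature unused in this tree
        perm.resize(no);
        for (int k = 0; k < no; ++k) perm[k] = k;
        for (int k = no - 1; k > 0; --k) {
          int j = (int)(unif_rand() * (k + 1));
          if (j > k) j = k;
          std::swap(perm[k], perm[j]);
        }
        Xp = NumericMatrix(1, p);
        double sse = 0.0;
        for (int k = 0; k < no; ++k) {
          int i = oob[k];
          for (int c = 0; c < p; ++c) Xp(0, c) = X(i, c);
          Xp(0, f) = X(oob[perm[k]], f);
          double e = y[i] - predict_one(tr, Xp, 0);
          sse += e * e;
        }
        oob_imp[f] += (sse - base) / no;
      }
    }
  }
  double s = sum(imp);
  NumericVector imp_norm = (s > 0) ? (NumericVector)(imp / s) : imp;
  return List::create(_["trees"] = trees, _["importance"] = imp_norm,
                      _["importance_raw"] = imp,
                      _["importance_oob"] = oob_imp);
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X) {
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tr = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_one(tr, X, i);
  }
  if (T > 0) out = out / (double)T;
  return out;
}

// Row-wise minimum of selected columns, excluding a participant's own
// column (self_col[i] is the 1-based column to skip for row i, or 0).
// Backs the per-fold Hamming-pool minimum-distance computation.
// [[Rcpp::export]]
NumericVector cpp_rowmin_pool(NumericMatrix D, IntegerVector cols,
                              IntegerVector self_col) {
  int n = D.nrow(), m = cols.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int k = 0; k < m; ++k) {
      int j = cols[k] - 1;
      if (self_col[i] == cols[k]) continue;
      double v = D(i, j);
      if (v < best) best = v;
    }
    out[i] = (best == R_PosInf) ? NA_REAL : best;
  }
  return out;
}
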