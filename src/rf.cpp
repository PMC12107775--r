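#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Compact CART random forest for classification with the Gini criterion.
// Trees are grown to purity on bootstrap samples, searching mtry randomly
// drawn features per node. Importance is mean decrease in impurity (MDI),
// i.e. the bootstrap-weighted Gini gain accumulated per feature, averaged
// over trees. All randomness comes from R's RNG stream, so results are
// reproducible under set.seed().

namespace {

struct Tree {
  std::vector<int> feat;     // split feature, -1 for leaf
  std::vector<double> thr;   // split threshold (go left if x <= thr)
  std::vector<int> left, right;
  std::vector<int> pred;     // leaf class (valid when feat == -1)
};

double gini_from_counts(const std::vector<int> &cnt, int n) {
  if (n <= 0) return 0.0;
  double g = 1.0;
  for (size_t c = 0; c < cnt.size(); ++c) {
    double p = static_cast<double>(cnt[c]) / n;
    g -= p * p;
  }
  return g;
}

// majority class; ties broken toward the smallest class index
int majority(const std::vector<int> &cnt) {
  int best = 0;
  for (size_t c = 1; c < cnt.size(); ++c)
    if (cnt[c] > cnt[best]) best = static_cast<int>(c);
  return best;
}

// partial Fisher-Yates draw of mtry indices from 0..p-1 without replacement
void sample_features(std::vector<int> &pool, int mtry, std::vector<int> &out) {
  int p = static_cast<int>(pool.size());
  for (int i = 0; i < mtry; ++i) {
    int j = i + static_cast<int>(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

struct Builder {
  const NumericMatrix &X;
  const IntegerVector &y;   // 0-based classes
  int nclass, mtry, ntotal;
  std::vector<double> &imp; // impurity importance accumulator
  Tree tree;
  std::vector<int> pool;    // feature index pool for sampling

  Builder(const NumericMatrix &X_, const IntegerVector &y_, int nclass_,
          int mtry_, std::vector<double> &imp_)
      : X(X_), y(y_), nclass(nclass_), mtry(mtry_), ntotal(0), imp(imp_) {
    pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) pool[j] = j;
  }

  int new_node() {
    tree.feat.push_back(-1);
    tree.thr.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(0);
    return static_cast<int>(tree.feat.size()) - 1;
  }

  int grow(std::vector<int> &idx) {
    int node = new_node();
    int n = static_cast<int>(idx.size());
    std::vector<int> cnt(nclass, 0);
    for (int i = 0; i < n; ++i) cnt[y[idx[i]]]++;
    double g_node = gini_from_counts(cnt, n);
    tree.pred[node] = majority(cnt);
    if (n < 2 || g_node <= 0.0) return node;

    std::vector<int> feats(mtry);
    sample_features(pool, mtry, feats);

    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;
    std::vector<std::pair<double, int> > vals(n);
    std::vector<int> lcnt(nclass, 0);

    for (int m = 0; m < mtry; ++m) {
      int f = feats[m];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      if (vals[0].first == vals[n - 1].first) continue;
      std::fill(lcnt.begin(), lcnt.end(), 0);
      for (int i = 0; i < n - 1; ++i) {
        lcnt[vals[i].second]++;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        double gl = 1.0, gr = 1.0;
        for (int c = 0; c < nclass; ++c) {
          double pl = static_cast<double>(lcnt[c]) / nl;
          double pr = static_cast<double>(cnt[c] - lcnt[c]) / nr;
          gl -= pl * pl;
          gr -= pr * pr;
        }
        double gain = g_node - (nl * gl + nr * gr) / n;
        if (gain > best_gain + 1e-15) {
          best_gain = gain;
          best_feat = f;
          best_thr = (vals[i].first + vals[i + 1].first) / 2.0;
        }
      }
    }
    if (best_feat < 0) return node;

    imp[best_feat] += best_gain * n / ntotal;
    std::vector<int> lidx, ridx;
    lidx.reserve(n);
    ridx.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], best_feat) <= best_thr) lidx.push_back(idx[i]);
      else ridx.push_back(idx[i]);
    }
    tree.feat[node] = best_feat;
    tree.thr[node] = best_thr;
    tree.left[node] = grow(lidx);
    tree.right[node] = grow(ridx);
    return node;
  }
};

int predict_tree(const Tree &t, const NumericMatrix &X, int row) {
  int node = 0;
  while (t.feat[node] >= 0)
    node = (X(row, t.feat[node]) <= t.thr[node]) ? t.left[node] : t.right[node];
  return t.pred[node];
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".rf_fit_predict_cpp")]]
List rf_fit_predict_cpp(NumericMatrix X, IntegerVector y, int nclass,
                        NumericMatrix Xtest, int ntree, int mtry) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::vector<double> imp(p, 0.0);
  int ntest = Xtest.nrow();
  std::vector<std::vector<int> > votes(ntest, std::vector<int>(nclass, 0));

  for (int t = 0; t < ntree; ++t) {
    Builder b(X, y, nclass, mtry, imp);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int j = static_cast<int>(unif_rand() * n);
      if (j >= n) j = n - 1;
      idx[i] = j;
    }
    b.ntotal = n;
    b.grow(idx);
    for (int i = 0; i < ntest; ++i)
      votes[i][predict_tree(b.tree, Xtest, i)]++;
  }

  IntegerVector pred(ntest);
  for (int i = 0; i < ntest; ++i) {
    int best = 0;
    for (int c = 1; c < nclass; ++c)
      if (votes[i][c] > votes[i][best]) best = c;
    pred[i] = best; // 0-based; ties toward smallest class index
  }
  NumericVector importance(p);
  for (int j = 0; j < p; ++j) importance[j] = imp[j] / ntree;
  return List::create(_["pred"] = pred, _["importance"] = importance);
}
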