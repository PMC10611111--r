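#include <Rcpp.h>
using namespace Rcpp;

// Random forest of CART trees: Gini impurity, bootstrap resampling, `mtry`
// features per split, trees grown to purity (or until no valid split).
// Feature importance is mean decrease of node impurity, normalized per
// tree. Uses R's RNG so results are reproducible under set.seed().
//
// Implementation notes: the bootstrap multiset is collapsed to unique rows
// with integer weights (weighted Gini is identical to the multiset Gini),
// node sample indices are partitioned in place, and all scratch buffers
// are reused across nodes and trees.

namespace {

struct SortRec {
  double v;
  int row;
  bool operator<(const SortRec& o) const { return v < o.v; }
};

struct Tree {
  std::vector<int> feature, left, right, pred;
  std::vector<double> threshold;
  int add_node() {
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    pred.push_back(-1); threshold.push_back(0.0);
    return (int)feature.size() - 1;
  }
  void clear() {
    feature.clear(); left.clear(); right.clear();
    pred.clear(); threshold.clear();
  }
};

class Builder {
public:
  Builder(const NumericMatrix& X, const IntegerVector& y, int K, int mtry)
    : imp_(X.ncol(), 0.0), X_(X), y_(y), K_(K), mtry_(mtry), p_(X.ncol()),
      feat_pool_(X.ncol()), cnt_(K), lc_(K) {
    for (int j = 0; j < p_; ++j) feat_pool_[j] = j;
    rec_.reserve(X.nrow());
  }

  Tree tree;
  std::vector<double> imp_;

  // idx/w: unique bootstrap rows and their multiplicities
  void build(std::vector<int>& idx, std::vector<double>& w) {
    idx_ = &idx; w_ = &w;
    std::fill(imp_.begin(), imp_.end(), 0.0);
    tree.clear();
    w_root_ = 0.0;
    for (int i = 0; i < (int)idx.size(); ++i) w_root_ += w[idx[i]];
    grow(0, (int)idx.size());
  }

private:
  const NumericMatrix& X_;
  const IntegerVector& y_;
  int K_, mtry_, p_;
  std::vector<int> feat_pool_;
  std::vector<double> cnt_, lc_;
  std::vector<SortRec> rec_;
  std::vector<int>* idx_ = nullptr;
  std::vector<double>* w_ = nullptr;
  double w_root_ = 0.0;

  static double gini_from_sumsq(double sumsq, double total) {
    return 1.0 - sumsq / (total * total);
  }

  int majority() const {
    int best = 0;
    for (int k = 1; k < K_; ++k) if (cnt_[k] > cnt_[best]) best = k;
    return best;
  }

  int grow(int lo, int hi) {
    std::vector<int>& idx = *idx_;
    const std::vector<double>& w = *w_;
    const int m = hi - lo;
    std::fill(cnt_.begin(), cnt_.end(), 0.0);
    double W = 0.0;
    for (int i = lo; i < hi; ++i) { cnt_[y_[idx[i]]] += w[idx[i]]; W += w[idx[i]]; }
    double sumsq = 0.0;
    for (int k = 0; k < K_; ++k) sumsq += cnt_[k] * cnt_[k];
    const double imp_node = gini_from_sumsq(sumsq, W);
    int node = tree.add_node();
    if (imp_node <= 1e-12 || m < 2) { tree.pred[node] = majority(); return node; }

    int best_f = -1;
    double best_thr = 0.0, best_gain = -1.0;
    for (int t = 0; t < mtry_; ++t) {
      int r = t + (int)(unif_rand() * (p_ - t));
      if (r >= p_) r = p_ - 1;
      std::swap(feat_pool_[t], feat_pool_[r]);
      const int f = feat_pool_[t];
      // cheap constant check before paying for a sort
      double vmin = X_(idx[lo], f), vmax = vmin;
      for (int i = lo + 1; i < hi; ++i) {
        double v = X_(idx[i], f);
        if (v < vmin) vmin = v; else if (v > vmax) vmax = v;
      }
      if (vmin == vmax) continue;
      rec_.resize(m);
      for (int i = 0; i < m; ++i) { rec_[i].v = X_(idx[lo + i], f); rec_[i].row = idx[lo + i]; }
      std::sort(rec_.begin(), rec_.end());
      std::fill(lc_.begin(), lc_.end(), 0.0);
      double wl = 0.0, sl = 0.0;           // left weight, left sum of squares
      for (int i = 0; i < m - 1; ++i) {
        const int c = y_[rec_[i].row];
        const double wi = w[rec_[i].row];
        sl += wi * (2.0 * lc_[c] + wi);    // incremental sum of squares
        lc_[c] += wi;
        wl += wi;
        if (rec_[i].v == rec_[i + 1].v) continue;
        const double wr = W - wl;
        double sr = 0.0;
        for (int k = 0; k < K_; ++k) {
          const double c2 = cnt_[k] - lc_[k];
          sr += c2 * c2;
        }
        const double gain = imp_node - (wl / W) * gini_from_sumsq(sl, wl)
                                     - (wr / W) * gini_from_sumsq(sr, wr);
        if (gain > best_gain) {
          best_gain = gain; best_f = f;
          best_thr = 0.5 * (rec_[i].v + rec_[i + 1].v);
        }
      }
    }
    if (best_f < 0) { tree.pred[node] = majority(); return node; }

    imp_[best_f] += (W / w_root_) * best_gain;

    // in-place partition of the node's index range
    int i = lo, j = hi - 1;
    const int f = best_f;
    while (i <= j) {
      if (X_(idx[i], f) <= best_thr) ++i;
      else std::swap(idx[i], idx[j--]);
    }
    // guard: both children non-empty (numerically guaranteed, but be safe)
    if (i == lo || i == hi) { tree.pred[node] = majority(); return node; }
    tree.feature[node] = f;
    tree.threshold[node] = best_thr;
    const int l = grow(lo, i);
    const int r = grow(i, hi);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

int predict_one(const Tree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(row, t.feature[node]) <= t.threshold[node]) ? t.left[node]
                                                          : t.right[node];
  return t.pred[node];
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_predict_cpp")]]
List rf_fit_predict_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                        NumericMatrix X_test, int n_trees, int mtry) {
  const int n = X.nrow(), p = X.ncol(), nt = X_test.nrow();
  if (n == 0) stop("empty training set");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  for (int i = 0; i < n; ++i)
    if (y[i] < 0 || y[i] >= n_classes) stop("label out of range");
  IntegerMatrix votes(nt, n_classes);
  NumericVector importance(p);
  Builder b(X, y, n_classes, mtry);
  std::vector<double> w(n);
  std::vector<int> idx;
  idx.reserve(n);
  for (int t = 0; t < n_trees; ++t) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      w[r] += 1.0;
    }
    idx.clear();
    for (int i = 0; i < n; ++i) if (w[i] > 0) idx.push_back(i);
    b.build(idx, w);
    double tot = 0.0;
    for (int j = 0; j < p; ++j) tot += b.imp_[j];
    if (tot > 0) for (int j = 0; j < p; ++j) importance[j] += b.imp_[j] / tot;
    for (int i = 0; i < nt; ++i) votes(i, predict_one(b.tree, X_test, i))++;
  }
  double isum = 0.0;
  for (int j = 0; j < p; ++j) isum += importance[j];
  if (isum > 0) for (int j = 0; j < p; ++j) importance[j] /= isum;
  return List::create(_["votes"] = votes, _["importance"] = importance);
}
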