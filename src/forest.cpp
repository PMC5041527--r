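// Regression random forest with out-of-bag prediction.
//
// CART regression trees on bootstrap resamples, variance-reduction splits,
// mtry candidate features per split, nodes of <= min_node observations kept
// as leaves. Randomness comes from R's RNG stream so set.seed() makes fits
// reproducible. Only the pieces the propensity-score machinery needs are
// implemented: fit + OOB predictions + prediction on new data.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> thresh;   // split: x <= thresh goes left
  std::vector<int> left, right; // child node ids
  std::vector<double> value;    // node mean of y
};

int rand_int(int n) {  // uniform on {0, ..., n-1} from R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Grow the subtree for idx[lo, hi); returns the node id.
int grow(Tree &t, const NumericMatrix &X, const NumericVector &y,
         std::vector<int> &idx, int lo, int hi, int mtry, int min_node,
         std::vector<int> &feat_pool,
         std::vector<std::pair<double, double> > &buf) {
  const int n = hi - lo;
  double sum = 0.0;
  for (int i = lo; i < hi; ++i) sum += y[idx[i]];
  const double mean = sum / n;

  const int id = (int)t.feature.size();
  t.feature.push_back(-1);
  t.thresh.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.value.push_back(mean);
  if (n <= min_node) return id;

  const int p = X.ncol();
  // partial Fisher-Yates to pick mtry distinct candidate features
  for (int j = 0; j < p; ++j) feat_pool[j] = j;
  int best_j = -1;
  double best_thresh = 0.0, best_score = -1.0;
  const double base = sum * sum / n;

  for (int m = 0; m < mtry; ++m) {
    const int r = m + rand_int(p - m);
    std::swap(feat_pool[m], feat_pool[r]);
    const int j = feat_pool[m];

    buf.clear();
    for (int i = lo; i < hi; ++i)
      buf.push_back(std::make_pair(X(idx[i], j), y[idx[i]]));
    std::sort(buf.begin(), buf.end());
    if (buf.front().first == buf.back().first) continue;  // constant feature

    double sl = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      sl += buf[k].second;
      if (buf[k].first == buf[k + 1].first) continue;     // not a boundary
      const int nl = k + 1, nr = n - nl;
      const double sr = sum - sl;
      const double score = sl * sl / nl + sr * sr / nr - base;
      if (score > best_score) {
        best_score = score;
        best_j = j;
        best_thresh = (buf[k].first + buf[k + 1].first) / 2.0;
      }
    }
  }
  if (best_j < 0 || best_score <= 0.0) return id;  // no useful split found

  // partition idx[lo, hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_j) <= best_thresh) {
      std::swap(idx[i], idx[mid]);
      ++mid;
    }
  }
  if (mid == lo || mid == hi) return id;  // numerical guard

  t.feature[id] = best_j;
  t.thresh[id] = best_thresh;
  t.left[id] = grow(t, X, y, idx, lo, mid, mtry, min_node, feat_pool, buf);
  t.right[id] = grow(t, X, y, idx, mid, hi, mtry, min_node, feat_pool, buf);
  return id;
}

double predict_one(const Tree &t, const NumericMatrix &X, int row) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(row, t.feature[node]) <= t.thresh[node]) ? t.left[node]
                                                       : t.right[node];
  return t.value[node];
}

List pack(const Tree &t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["thresh"] = wrap(t.thresh),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value));
}

Tree unpack(const List &l) {
  Tree t;
  t.feature = as<std::vector<int> >(l["feature"]);
  t.thresh = as<std::vector<double> >(l["thresh"]);
  t.left = as<std::vector<int> >(l["left"]);
  t.right = as<std::vector<int> >(l["right"]);
  t.value = as<std::vector<double> >(l["value"]);
  return t;
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_node) {
  const int n = X.nrow();
  List trees(ntree);
  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_n(n, 0);
  std::vector<int> idx(n), feat_pool(X.ncol());
  std::vector<char> inbag(n);
  std::vector<std::pair<double, double> > buf;
  buf.reserve(n);

  for (int b = 0; b < ntree; ++b) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      const int k = rand_int(n);
      idx[i] = k;
      inbag[k] = 1;
    }
    Tree t;
    grow(t, X, y, idx, 0, n, mtry, min_node, feat_pool, buf);
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        oob_sum[i] += predict_one(t, X, i);
        oob_n[i] += 1;
      }
    }
    trees[b] = pack(t);
  }
  return List::create(_["trees"] = trees, _["oob_sum"] = oob_sum,
                      _["oob_n"] = oob_n);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int B = trees.size();
  NumericVector out(n, 0.0);
  for (int b = 0; b < B; ++b) {
    Tree t = unpack(trees[b]);
    for (int i = 0; i < n; ++i) out[i] += predict_one(t, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}
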