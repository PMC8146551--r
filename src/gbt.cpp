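#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Regularized structure score contribution of one leaf: -G^2 / (2(H + lambda)).
static inline double leaf_score(double G, double H, double lambda) {
  return -0.5 * G * G / (H + lambda);
}

struct SplitResult {
  bool found;
  int feature;      // 0-based
  double threshold;
  double gain;
  double GL, HL, GR, HR;
};

// Exact greedy enumeration over all features and all midpoints between
// consecutive distinct sorted values, given per-feature row lists already
// sorted by feature value. Ties broken by lower feature index, then lower
// threshold (guaranteed by scanning features and thresholds in ascending
// order and accepting only strictly larger gains). min_child = 1 row/side.
static SplitResult best_split_sorted(const NumericMatrix& X,
                                     const NumericVector& g,
                                     const NumericVector& h,
                                     const std::vector<std::vector<int> >& lists,
                                     double lambda, double gamma) {
  SplitResult best;
  best.found = false;
  best.gain = 0.0;
  const int n = lists.empty() ? 0 : (int) lists[0].size();
  if (n < 2) return best;

  double G = 0.0, H = 0.0;
  for (int i = 0; i < n; ++i) { G += g[lists[0][i]]; H += h[lists[0][i]]; }
  const double parent = leaf_score(G, H, lambda);

  for (size_t p = 0; p < lists.size(); ++p) {
    const std::vector<int>& ord = lists[p];
    double GL = 0.0, HL = 0.0;
    for (int i = 0; i + 1 < n; ++i) {
      GL += g[ord[i]];
      HL += h[ord[i]];
      const double v = X(ord[i], p), vnext = X(ord[i + 1], p);
      if (v == vnext) continue;  // not a boundary between distinct values
      const double net = parent - (leaf_score(GL, HL, lambda) +
                                   leaf_score(G - GL, H - HL, lambda));
      const double gain = net - gamma;
      if (gain > best.gain) {
        best.found = true;
        best.feature = (int) p;
        best.threshold = v + 0.5 * (vnext - v);
        best.gain = gain;
        best.GL = GL; best.HL = HL; best.GR = G - GL; best.HR = H - HL;
      }
    }
  }
  return best;
}

struct TreeBuilder {
  std::vector<int> feature;        // -1 for leaf
  std::vector<double> threshold;
  std::vector<double> weight;      // leaf weight (unscaled Newton step)
  std::vector<double> gain;
  std::vector<int> left, right;    // 1-based child ids, 0 for leaf

  int add_node() {
    feature.push_back(-1); threshold.push_back(NA_REAL);
    weight.push_back(NA_REAL); gain.push_back(NA_REAL);
    left.push_back(0); right.push_back(0);
    return (int) feature.size() - 1;
  }
};

static void grow(TreeBuilder& tb, int node,
                 const NumericMatrix& X, const NumericVector& g,
                 const NumericVector& h,
                 std::vector<std::vector<int> >& lists,
                 int depth, int max_depth, double lambda, double gamma) {
  const int n = (int) lists[0].size();
  double G = 0.0, H = 0.0;
  for (int i = 0; i < n; ++i) { G += g[lists[0][i]]; H += h[lists[0][i]]; }

  SplitResult sp;
  sp.found = false;
  if (depth < max_depth && n >= 2)
    sp = best_split_sorted(X, g, h, lists, lambda, gamma);

  if (!sp.found) {
    tb.weight[node] = -G / (H + lambda);
    return;
  }
  tb.feature[node] = sp.feature;
  tb.threshold[node] = sp.threshold;
  tb.gain[node] = sp.gain;

  // partition every feature's sorted list, preserving order
  const int p = (int) lists.size();
  std::vector<std::vector<int> > llists(p), rlists(p);
  for (int j = 0; j < p; ++j) {
    llists[j].reserve(n); rlists[j].reserve(n);
    for (int i = 0; i < n; ++i) {
      const int row = lists[j][i];
      if (X(row, sp.feature) < sp.threshold) llists[j].push_back(row);
      else rlists[j].push_back(row);
    }
  }
  { std::vector<std::vector<int> > tmp; lists.swap(tmp); }  // free parent

  const int l = tb.add_node(), r = tb.add_node();
  tb.left[node] = l + 1;
  tb.right[node] = r + 1;
  grow(tb, l, X, g, h, llists, depth + 1, max_depth, lambda, gamma);
  grow(tb, r, X, g, h, rlists, depth + 1, max_depth, lambda, gamma);
}

static std::vector<std::vector<int> > presort(const NumericMatrix& X) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<int> > lists(p);
  for (int j = 0; j < p; ++j) {
    lists[j].resize(n);
    for (int i = 0; i < n; ++i) lists[j][i] = i;
    const NumericMatrix::ConstColumn col = X.column(j);
    std::stable_sort(lists[j].begin(), lists[j].end(),
                     [&](int a, int b) { return col[a] < col[b]; });
  }
  return lists;
}

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, NumericVector g, NumericVector h,
                   int max_depth, double lambda, double gamma) {
  TreeBuilder tb;
  tb.add_node();
  std::vector<std::vector<int> > lists = presort(X);
  grow(tb, 0, X, g, h, lists, 0, max_depth, lambda, gamma);
  return List::create(
    _["feature"] = IntegerVector(tb.feature.begin(), tb.feature.end()),
    _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
    _["weight"] = NumericVector(tb.weight.begin(), tb.weight.end()),
    _["gain"] = NumericVector(tb.gain.begin(), tb.gain.end()),
    _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
    _["right"] = IntegerVector(tb.right.begin(), tb.right.end()));
}

// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, NumericVector g, NumericVector h,
                    double lambda, double gamma) {
  std::vector<std::vector<int> > lists = presort(X);
  SplitResult sp = best_split_sorted(X, g, h, lists, lambda, gamma);
  if (!sp.found) return List::create(_["found"] = false);
  return List::create(
    _["found"] = true, _["feature"] = sp.feature + 1,
    _["threshold"] = sp.threshold, _["gain"] = sp.gain,
    _["GL"] = sp.GL, _["HL"] = sp.HL, _["GR"] = sp.GR, _["HR"] = sp.HR);
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(NumericMatrix X, IntegerVector feature,
                               NumericVector threshold, NumericVector weight,
                               IntegerVector left, IntegerVector right) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) < threshold[node] ? left[node] : right[node]) - 1;
    out[i] = weight[node];
  }
  return out;
}
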