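#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Per-feature sample ordering, computed once per training set so each
// boosting round is a linear sweep.
// [[Rcpp::export]]
IntegerMatrix cpp_stump_order(NumericMatrix X) {
  int n = X.nrow(), d = X.ncol();
  IntegerMatrix ord(n, d);
  std::vector<int> idx(n);
  for (int j = 0; j < d; ++j) {
    std::iota(idx.begin(), idx.end(), 0);
    const double* col = &X(0, j);
    std::stable_sort(idx.begin(), idx.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
    for (int i = 0; i < n; ++i) ord(i, j) = idx[i];
  }
  return ord;
}

// Exhaustive decision-stump search: minimizes weighted 0-1 error over
// (feature, threshold, polarity). Polarity +1 predicts positive when
// x >= threshold, polarity -1 when x < threshold. Weights must sum to 1.
// [[Rcpp::export]]
List cpp_best_stump(NumericMatrix X, IntegerMatrix ord, NumericVector w,
                    IntegerVector y) {
  int n = X.nrow(), d = X.ncol();
  double Wn = 0.0;
  for (int i = 0; i < n; ++i)
    if (y[i] < 0) Wn += w[i];
  double best_err = R_PosInf, best_thr = 0.0;
  int best_feat = 0, best_pol = 1;
  for (int j = 0; j < d; ++j) {
    const double* col = &X(0, j);
    const int* o = &ord(0, j);
    // err for polarity +1 with threshold below all samples: all accepted
    double err = Wn;
    // threshold below the minimum
    {
      double e1 = err, e2 = 1.0 - err;
      double thr = col[o[0]] - 1.0;
      if (e1 < best_err) { best_err = e1; best_feat = j; best_thr = thr; best_pol = 1; }
      if (e2 < best_err) { best_err = e2; best_feat = j; best_thr = thr; best_pol = -1; }
    }
    for (int i = 0; i < n; ++i) {
      int k = o[i];
      err += (y[k] > 0) ? w[k] : -w[k];
      // threshold between x[o[i]] and the next distinct value
      if (i < n - 1 && col[o[i + 1]] == col[k]) continue;
      double thr = (i < n - 1) ? 0.5 * (col[k] + col[o[i + 1]]) : col[k] + 1.0;
      double e1 = err, e2 = 1.0 - err;
      if (e1 < best_err) { best_err = e1; best_feat = j; best_thr = thr; best_pol = 1; }
      if (e2 < best_err) { best_err = e2; best_feat = j; best_thr = thr; best_pol = -1; }
    }
  }
  return List::create(_["feature"] = best_feat + 1, _["threshold"] = best_thr,
                      _["polarity"] = best_pol, _["error"] = best_err);
}
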