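// Circular binary segmentation: max-|Z| arc scan with permutation p-value.
// The arc statistic for the arc (i+1)..j against its complement, with the
// overall variance held fixed, is
//   Z(i,j) = |S_j - S_i - m/n * S_n| / sqrt(m (1 - m/n)),  m = j - i,
// which is a monotone transform of the two-sample t statistic under
// permutation (the variance term is permutation-invariant and cancels).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static double max_arc_stat(const std::vector<double>& x, int* bi, int* bj) {
  int n = (int)x.size();
  std::vector<double> S(n + 1, 0.0);
  for (int k = 0; k < n; ++k) S[k + 1] = S[k] + x[k];
  double tot = S[n];
  double best = -1.0;
  int besti = 0, bestj = 1;
  for (int m = 1; m < n; ++m) {
    double den = std::sqrt((double)m * (1.0 - (double)m / n));
    double frac = (double)m * tot / n;
    for (int i = 0; i + m <= n; ++i) {
      int j = i + m;
      double z = std::fabs(S[j] - S[i] - frac) / den;
      if (z > best) { best = z; besti = i; bestj = j; }
    }
  }
  if (bi) *bi = besti;
  if (bj) *bj = bestj;
  return best;
}

// [[Rcpp::export]]
List cbs_scan(NumericVector x, int nperm, double alpha) {
  int n = x.size();
  if (n < 2) return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = n,
                                 _["p"] = 1.0);
  std::vector<double> v(x.begin(), x.end());
  int bi, bj;
  double obs = max_arc_stat(v, &bi, &bj);
  int kmax = (int)std::floor(alpha * nperm);
  int exceed = 0, done = 0;
  RNGScope scope;
  std::vector<double> y(v);
  for (int p = 0; p < nperm; ++p) {
    for (int k = n - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(y[k], y[idx]);
    }
    double m = max_arc_stat(y, nullptr, nullptr);
    ++done;
    if (m >= obs - 1e-12) ++exceed;
    if (exceed > kmax) break;  // p-value can no longer drop below alpha
  }
  return List::create(_["stat"] = obs, _["i"] = bi, _["j"] = bj,
                      _["p"] = (double)exceed / (double)done);
}
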