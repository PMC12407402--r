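#include <Rcpp.h>
using namespace Rcpp;

// Alternating within-group demeaning over one or two fixed-effect factors.
// Groups are 0-based integer codes. Convergence: the largest absolute
// adjustment applied during a full sweep falls below tol.
// [[Rcpp::export]]
List demean_cpp(NumericMatrix M_in, IntegerVector g1, IntegerVector g2,
                int L1, int L2, double tol, int max_sweeps) {
  NumericMatrix M = clone(M_in);
  const int n = M.nrow(), p = M.ncol();
  const bool two = (L2 > 0);

  std::vector<double> cnt1(L1, 0.0), cnt2(two ? L2 : 0, 0.0);
  for (int i = 0; i < n; ++i) {
    cnt1[g1[i]] += 1.0;
    if (two) cnt2[g2[i]] += 1.0;
  }
  std::vector<double> sum1(L1), sum2(two ? L2 : 0);

  double delta = R_PosInf;
  int sweeps = 0;
  while (sweeps < max_sweeps) {
    ++sweeps;
    delta = 0.0;
    for (int j = 0; j < p; ++j) {
      double *col = &M(0, j);
      std::fill(sum1.begin(), sum1.end(), 0.0);
      for (int i = 0; i < n; ++i) sum1[g1[i]] += col[i];
      for (int l = 0; l < L1; ++l) sum1[l] /= cnt1[l];
      for (int i = 0; i < n; ++i) {
        double a = sum1[g1[i]];
        col[i] -= a;
        double aa = std::fabs(a);
        if (aa > delta) delta = aa;
      }
      if (two) {
        std::fill(sum2.begin(), sum2.end(), 0.0);
        for (int i = 0; i < n; ++i) sum2[g2[i]] += col[i];
        for (int l = 0; l < L2; ++l) sum2[l] /= cnt2[l];
        for (int i = 0; i < n; ++i) {
          double a = sum2[g2[i]];
          col[i] -= a;
          double aa = std::fabs(a);
          if (aa > delta) delta = aa;
        }
      }
    }
    if (delta < tol) break;
  }
  return List::create(_["M"] = M, _["sweeps"] = sweeps, _["delta"] = delta);
}
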