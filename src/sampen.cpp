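#include <Rcpp.h>
using namespace Rcpp;

// Template-pair counts for sample entropy.
//
// Templates X_i = [x_i, x_{i+tau}, ..., x_{i+(m-1)tau}] for
// i = 1..N - m*tau (the m+1-length count runs over the same template
// indices, so the two counts are ratios over a common denominator of
// pairs). Counts unordered pairs i < j whose Chebyshev distance is <= r
// at length m (countB) and at length m+1 (countA).
//
// [[Rcpp::export]]
NumericVector sampen_pair_counts(NumericVector x, int m, int tau, double r) {
  const int n = x.size();
  const int ntempl = n - m * tau;  // templates with an (m+1)-th point available
  double countA = 0.0, countB = 0.0;
  for (int i = 0; i < ntempl - 1; ++i) {
    for (int j = i + 1; j < ntempl; ++j) {
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k * tau] - x[j + k * tau]) > r) {
          match_m = false;
          break;
        }
      }
      if (!match_m) continue;
      countB += 1.0;
      if (std::fabs(x[i + m * tau] - x[j + m * tau]) <= r) countA += 1.0;
    }
  }
  return NumericVector::create(countA, countB);
}
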