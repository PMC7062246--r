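// Kendall tau-b by direct O(n^2) pair enumeration. The screening tables in
// this workflow are a few thousand rows, where the quadratic loop runs in
// milliseconds; tau-b's tie corrections come out of the same pass.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_kendall_tau_b")]]
double cpp_kendall_tau_b(NumericVector x, NumericVector y) {
  int n = x.size();
  long long concordant = 0, discordant = 0, tx = 0, ty = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx == 0.0 && dy == 0.0) continue;       // tied in both: excluded
      else if (dx == 0.0) ++tx;
      else if (dy == 0.0) ++ty;
      else if (dx * dy > 0.0) ++concordant;
      else ++discordant;
    }
  }
  double n0 = 0.5 * (double)n * (n - 1);
  long long txy = (long long)n0 - concordant - discordant - tx - ty;
  double denom = std::sqrt((n0 - (double)(tx + txy)) * (n0 - (double)(ty + txy)));
  if (denom <= 0.0) return NA_REAL;
  return (double)(concordant - discordant) / denom;
}
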