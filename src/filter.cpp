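#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Direct-form II transposed IIR filter with initial conditions.
// b and a must have equal length n, a[0] == 1; zi has length n - 1.
// [[Rcpp::export]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  const int n = b.size();
  const int T = x.size();
  std::vector<double> z(zi.begin(), zi.end());
  NumericVector y(T);
  for (int t = 0; t < T; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + z[0];
    for (int i = 1; i < n - 1; ++i)
      z[i - 1] = b[i] * xt + z[i] - a[i] * yt;
    z[n - 2] = b[n - 1] * xt - a[n - 1] * yt;
    y[t] = yt;
  }
  return y;
}
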