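#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed biquad with explicit initial state; a[0] must
// be 1. The caller supplies the state (typically the steady-state
// response to the first sample, which suppresses startup transients for
// filters with poles close to the unit circle).
// [[Rcpp::export]]
NumericVector cpp_biquad(NumericVector x, NumericVector b, NumericVector a,
                         NumericVector zi) {
  const int n = x.size();
  double z1 = zi[0], z2 = zi[1];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + z1;
    z1 = b[1] * xt - a[1] * yt + z2;
    z2 = b[2] * xt - a[2] * yt;
    y[t] = yt;
  }
  return y;
}
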