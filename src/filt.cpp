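#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, a[0] assumed 1.
// zi: initial filter state (length max(nb, na) - 1), or empty for zeros.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nw = std::max(nb, na) - 1;
  std::vector<double> w(nw, 0.0);
  if (zi.size() == (R_xlen_t)nw)
    for (int k = 0; k < nw; ++k) w[k] = zi[k];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = b[0] * xt + (nw > 0 ? w[0] : 0.0);
    for (int k = 0; k < nw; ++k) {
      double wk = (k + 1 < nw) ? w[k + 1] : 0.0;
      double bv = (k + 1 < nb) ? b[k + 1] : 0.0;
      double av = (k + 1 < na) ? a[k + 1] : 0.0;
      w[k] = wk + bv * xt - av * yt;
    }
    y[t] = yt;
  }
  return y;
}
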