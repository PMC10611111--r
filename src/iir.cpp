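#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with optional initial state
// (a[0] is normalized away internally).
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x,
                             Nullable<NumericVector> zi = R_NilValue) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nw = std::max(nb, na) - 1;
  std::vector<double> bb(nw + 1, 0.0), aa(nw + 1, 0.0), w(nw, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  if (zi.isNotNull()) {
    NumericVector z(zi);
    if (z.size() != nw) stop("zi has wrong length");
    for (int i = 0; i < nw; ++i) w[i] = z[i];
  }
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nw > 0 ? w[0] : 0.0);
    for (int k = 0; k < nw - 1; ++k)
      w[k] = bb[k + 1] * xi + w[k + 1] - aa[k + 1] * yi;
    if (nw > 0) w[nw - 1] = bb[nw] * xi - aa[nw] * yi;
    y[i] = yi;
  }
  return y;
}
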