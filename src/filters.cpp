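#include <Rcpp.h>
using namespace Rcpp;

// Direct form II transposed IIR filter with initial conditions.
// a[0] must be 1 (normalisation happens on the R side).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  const int n = x.size();
  const int nb = b.size();
  const int na = a.size();
  const int nz = zi.size();
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = (nz > 0) ? b[0] * xi + z[0] : b[0] * xi;
    for (int k = 0; k < nz; ++k) {
      double acc = (k + 1 < nz) ? z[k + 1] : 0.0;
      if (k + 1 < nb) acc += b[k + 1] * xi;
      if (k + 1 < na) acc -= a[k + 1] * yi;
      z[k] = acc;
    }
    y[i] = yi;
  }
  return y;
}
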