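#include <Rcpp.h>
using namespace Rcpp;

// Direct form II transposed IIR filter. a[0] must be 1. zi has length
// max(length(a), length(b)) - 1 and carries the initial filter state
// (scipy lfilter_zi convention), so filtfilt can start in steady state.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nf = std::max(na, nb);
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nf - 1, 0.0);
  if (zi.size() != (R_xlen_t)(nf - 1)) stop("zi has wrong length");
  for (int i = 0; i < nf - 1; ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nf - 2; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}
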