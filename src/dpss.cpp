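#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Discrete prolate spheroidal sequences via the symmetric tridiagonal
// eigenproblem (Slepian's commuting tridiagonal matrix):
//   diag[t]  = ((N-1-2t)/2)^2 * cos(2*pi*W),  t = 0..N-1
//   offdg[t] = t*(N-t)/2,                     t = 1..N-1
// The K eigenvectors of largest eigenvalue are the first K tapers.
// Returns an N x K matrix, tapers normalized to unit energy.
// [[Rcpp::export(name = ".dpss_tridiag")]]
arma::mat dpss_tridiag(int n, double nw, int k) {
  double W = nw / n;
  arma::mat T(n, n, arma::fill::zeros);
  double c = std::cos(2.0 * M_PI * W);
  for (int t = 0; t < n; ++t) {
    double d = (n - 1 - 2.0 * t) / 2.0;
    T(t, t) = d * d * c;
  }
  for (int t = 1; t < n; ++t) {
    double e = t * (n - t) / 2.0;
    T(t, t - 1) = e;
    T(t - 1, t) = e;
  }
  arma::vec eigval;
  arma::mat eigvec;
  arma::eig_sym(eigval, eigvec, T);  // ascending
  arma::mat out(n, k);
  for (int j = 0; j < k; ++j) {
    arma::vec v = eigvec.col(n - 1 - j);
    // polarity convention: positive mean for symmetric tapers, positive
    // initial slope for antisymmetric ones
    double s = arma::accu(v);
    if (std::fabs(s) > 1e-10) {
      if (s < 0) v = -v;
    } else if (v(1) - v(0) < 0) {
      v = -v;
    }
    out.col(j) = v / arma::norm(v);
  }
  return out;
}
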