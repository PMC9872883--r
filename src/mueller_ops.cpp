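// Per-pixel 4x4 matrix exponential / principal logarithm over image stacks.
// Matrices travel as 16 x N column-major stacks (column = one pixel, the 4x4
// unrolled column-major), which keeps the R <-> C++ boundary copy-free-ish and
// lets a whole Mueller map be transformed in one call.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// [[Rcpp::export(name = ".expm_stack")]]
NumericMatrix expm_stack(const NumericMatrix& G) {
  if (G.nrow() != 16) stop("generator stack must be 16 x N");
  const int n = G.ncol();
  NumericMatrix out(16, n);
  arma::mat A(4, 4);
  for (int j = 0; j < n; ++j) {
    std::copy(G.column(j).begin(), G.column(j).end(), A.memptr());
    arma::mat E = arma::expmat(A);
    std::copy(E.memptr(), E.memptr() + 16, out.column(j).begin());
  }
  return out;
}

// Principal matrix logarithm; a column is filled with NaN when the logarithm
// does not exist or its imaginary residual exceeds `tol` (non-physical pixel).
// [[Rcpp::export(name = ".logm_stack")]]
NumericMatrix logm_stack(const NumericMatrix& F, const double tol) {
  if (F.nrow() != 16) stop("matrix stack must be 16 x N");
  const int n = F.ncol();
  NumericMatrix out(16, n);
  arma::mat A(4, 4);
  arma::cx_mat L;
  for (int j = 0; j < n; ++j) {
    std::copy(F.column(j).begin(), F.column(j).end(), A.memptr());
    bool ok = A.is_finite() && arma::logmat(L, A);
    if (ok) {
      double resid = arma::norm(arma::imag(L), "fro");
      ok = std::isfinite(resid) && (resid <= tol);
    }
    if (ok) {
      arma::mat Lr = arma::real(L);
      std::copy(Lr.memptr(), Lr.memptr() + 16, out.column(j).begin());
    } else {
      std::fill(out.column(j).begin(), out.column(j).end(), NA_REAL);
    }
  }
  return out;
}
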