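// Small dense kernels for the encoder hot path: affine map with row
// bias, layer normalization (forward/backward) and exact GELU.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_linear")]]
arma::mat cpp_linear(const arma::mat& X, const arma::mat& W,
                     Nullable<NumericVector> b) {
  arma::mat Y = X * W;
  if (b.isNotNull()) {
    NumericVector bv(b);
    arma::rowvec br(bv.begin(), bv.size());
    Y.each_row() += br;
  }
  return Y;
}

static const double LN_EPS = 1e-5;

// [[Rcpp::export(name = ".cpp_ln_fwd")]]
List cpp_ln_fwd(const arma::mat& X, const arma::vec& g, const arma::vec& b) {
  arma::vec mu = arma::mean(X, 1);
  arma::mat xc = X.each_col() - mu;
  arma::vec v = arma::mean(xc % xc, 1);
  arma::vec inv = 1.0 / arma::sqrt(v + LN_EPS);
  arma::mat xhat = xc.each_col() % inv;
  arma::mat y = xhat.each_row() % g.t();
  y.each_row() += b.t();
  return List::create(Named("y") = y, Named("xhat") = xhat,
                      Named("inv") = inv);
}

// [[Rcpp::export(name = ".cpp_ln_bwd")]]
List cpp_ln_bwd(const arma::mat& dY, const arma::mat& xhat,
                const arma::vec& inv, const arma::vec& g) {
  arma::mat dxhat = dY.each_row() % g.t();
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % xhat, 1);
  arma::mat dX = dxhat.each_col() - m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= inv;
  arma::rowvec dg = arma::sum(dY % xhat, 0);
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(Named("dX") = dX,
                      Named("dg") = arma::vec(dg.t()),
                      Named("db") = arma::vec(db.t()));
}

static inline double phi(double x) {
  return 0.5 * (1.0 + std::erf(x * M_SQRT1_2));
}

// [[Rcpp::export(name = ".cpp_gelu_fwd")]]
arma::mat cpp_gelu_fwd(const arma::mat& X) {
  arma::mat Y(X.n_rows, X.n_cols);
  const double* xp = X.memptr();
  double* yp = Y.memptr();
  const size_t n = X.n_elem;
  for (size_t i = 0; i < n; ++i) yp[i] = xp[i] * phi(xp[i]);
  return Y;
}

// [[Rcpp::export(name = ".cpp_gelu_bwd")]]
arma::mat cpp_gelu_bwd(const arma::mat& dY, const arma::mat& X) {
  arma::mat dX(X.n_rows, X.n_cols);
  const double* xp = X.memptr();
  const double* dp = dY.memptr();
  double* op = dX.memptr();
  const size_t n = X.n_elem;
  const double c = 1.0 / std::sqrt(2.0 * M_PI);
  for (size_t i = 0; i < n; ++i) {
    double x = xp[i];
    op[i] = dp[i] * (phi(x) + x * c * std::exp(-0.5 * x * x));
  }
  return dX;
}
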