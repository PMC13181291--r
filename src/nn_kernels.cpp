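// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Convolution forward: gather the padded input into im2col layout by the
// precomputed 1-based index matrix, then one BLAS product plus bias.
// [[Rcpp::export(name = ".cppConvFwd")]]
arma::mat cppConvFwd(const arma::vec& xp, const IntegerMatrix& idx,
                     const arma::mat& W, const arma::vec& b) {
  int n = idx.nrow(), m = idx.ncol();
  arma::mat col(n, m);
  for (int j = 0; j < m; ++j) {
    double* cj = col.colptr(j);
    const int* ij = &idx(0, j);
    for (int i = 0; i < n; ++i) cj[i] = xp[ij[i] - 1];
  }
  arma::mat y = col * W;
  y.each_row() += b.t();
  return y;
}

// Convolution backward: recompute the im2col matrix, return weight/bias
// gradients and the padded-input gradient (scatter-add of dcol).
// [[Rcpp::export(name = ".cppConvBwd")]]
List cppConvBwd(const arma::vec& xp, const IntegerMatrix& idx,
                const arma::mat& W, const arma::mat& dy, int nxp) {
  int n = idx.nrow(), m = idx.ncol();
  arma::mat col(n, m);
  for (int j = 0; j < m; ++j) {
    double* cj = col.colptr(j);
    const int* ij = &idx(0, j);
    for (int i = 0; i < n; ++i) cj[i] = xp[ij[i] - 1];
  }
  arma::mat dW = col.t() * dy;
  arma::vec db = arma::sum(dy, 0).t();
  arma::mat dcol = dy * W.t();
  arma::vec dxp(nxp, arma::fill::zeros);
  for (int j = 0; j < m; ++j) {
    const double* cj = dcol.colptr(j);
    const int* ij = &idx(0, j);
    for (int i = 0; i < n; ++i) dxp[ij[i] - 1] += cj[i];
  }
  return List::create(Named("dW") = dW, Named("db") = db, Named("dxp") = dxp);
}

// Instance normalization forward over an [HW, C*N] matrix; returns the
// normalized output plus xhat and 1/sd for the backward pass.
// [[Rcpp::export(name = ".cppInormFwd")]]
List cppInormFwd(const arma::mat& x, const arma::vec& g, const arma::vec& b,
                 const IntegerVector& chIdx, double eps) {
  int hw = x.n_rows, cn = x.n_cols;
  arma::mat xhat(hw, cn), y(hw, cn);
  arma::vec istd(cn);
  for (int j = 0; j < cn; ++j) {
    const double* xj = x.colptr(j);
    double mu = 0, m2 = 0;
    for (int i = 0; i < hw; ++i) mu += xj[i];
    mu /= hw;
    for (int i = 0; i < hw; ++i) { double d = xj[i] - mu; m2 += d * d; }
    double is = 1.0 / std::sqrt(m2 / hw + eps);
    istd[j] = is;
    double gj = g[chIdx[j] - 1], bj = b[chIdx[j] - 1];
    double* hj = xhat.colptr(j);
    double* yj = y.colptr(j);
    for (int i = 0; i < hw; ++i) {
      hj[i] = (xj[i] - mu) * is;
      yj[i] = gj * hj[i] + bj;
    }
  }
  return List::create(Named("y") = y, Named("xhat") = xhat,
                      Named("istd") = istd);
}

// Instance normalization backward.
// [[Rcpp::export(name = ".cppInormBwd")]]
List cppInormBwd(const arma::mat& dy, const arma::mat& xhat,
                 const arma::vec& istd, const arma::vec& g,
                 const IntegerVector& chIdx, int nCh) {
  int hw = dy.n_rows, cn = dy.n_cols;
  arma::mat dx(hw, cn);
  arma::vec dg(nCh, arma::fill::zeros), db(nCh, arma::fill::zeros);
  for (int j = 0; j < cn; ++j) {
    const double* dj = dy.colptr(j);
    const double* hj = xhat.colptr(j);
    double gj = g[chIdx[j] - 1];
    double s1 = 0, s2 = 0, sdg = 0, sdb = 0;
    for (int i = 0; i < hw; ++i) {
      sdg += dj[i] * hj[i];
      sdb += dj[i];
      s1 += dj[i] * gj;
      s2 += dj[i] * gj * hj[i];
    }
    dg[chIdx[j] - 1] += sdg;
    db[chIdx[j] - 1] += sdb;
    double m1 = s1 / hw, m2 = s2 / hw, is = istd[j];
    double* xj = dx.colptr(j);
    for (int i = 0; i < hw; ++i)
      xj[i] = is * (dj[i] * gj - m1 - hj[i] * m2);
  }
  return List::create(Named("dx") = dx, Named("dg") = dg, Named("db") = db);
}
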