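// Monte Carlo forward model for the constrained tensor-variate signal and the
// analytic gradient of its least-squares objective. Hot path of model fitting:
// everything here is O(n_mc * n_bmatrices) with blocked BLAS calls.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Positive-semidefiniteness of the symmetric 3x3 tensor encoded as
// (dxx, dyy, dzz, dxy, dxz, dyz), tested via the invariants of D + tol*I:
// a real-rooted cubic has all roots >= 0 iff I1, I2, I3 >= 0.
static inline bool psd6(const double* d, double tol) {
  const double a = d[0] + tol, b = d[1] + tol, c = d[2] + tol;
  const double f = d[3], g = d[4], h = d[5];
  const double I1 = a + b + c;
  if (I1 < 0.0) return false;
  const double I2 = a * b + a * c + b * c - f * f - g * g - h * h;
  if (I2 < 0.0) return false;
  const double I3 = a * (b * c - h * h) - f * (f * c - h * g) + g * (f * h - b * g);
  return I3 >= 0.0;
}

// [[Rcpp::export]]
LogicalVector cpp_psd_filter(const arma::mat& D, double tol) {
  const arma::uword n = D.n_rows;
  LogicalVector keep(n);
  for (arma::uword i = 0; i < n; ++i) {
    double d[6];
    for (int k = 0; k < 6; ++k) d[k] = D(i, k);
    keep[i] = psd6(d, tol);
  }
  return keep;
}

// Mean MC signal (s0 = 1) for proposals D (n x 6) against b-vectors Bv (N x 6,
// off-diagonals already doubled). Non-PSD proposals are rejected, mirroring
// the indicator in the signal integral.
// [[Rcpp::export]]
List cpp_mc_signal(const arma::mat& D, const arma::mat& Bv, double tol) {
  const arma::uword n = D.n_rows, N = Bv.n_rows;
  arma::vec acc_sum(N, arma::fill::zeros);
  const arma::uword blk = 2048;
  arma::uword n_acc = 0;
  for (arma::uword lo = 0; lo < n; lo += blk) {
    const arma::uword hi = std::min(lo + blk, n) - 1;
    arma::mat Db = D.rows(lo, hi);
    std::vector<arma::uword> keep;
    keep.reserve(Db.n_rows);
    for (arma::uword i = 0; i < Db.n_rows; ++i) {
      double d[6];
      for (int k = 0; k < 6; ++k) d[k] = Db(i, k);
      if (psd6(d, tol)) keep.push_back(i);
    }
    if (keep.empty()) continue;
    arma::uvec kk(keep);
    arma::mat E = arma::exp(-(Db.rows(kk) * Bv.t()));
    acc_sum += arma::sum(E, 0).t();
    n_acc += kk.n_elem;
  }
  arma::vec m = n_acc > 0 ? arma::vec(acc_sum / double(n_acc))
                          : arma::vec(N, arma::fill::zeros);
  return List::create(_["m"] = m, _["n_acc"] = (double)n_acc,
                      _["acc_frac"] = n > 0 ? (double)n_acc / (double)n : 0.0);
}

// Residual sum of squares of S_obs against s0 * m(theta) with s0 profiled out,
// plus the analytic gradient with respect to the mean 6-vector and the 6x6
// covariance factor L (samples d_i = dbar + L z_i, z fixed: common random
// numbers). The indicator's dependence on (dbar, L) is a measure-zero boundary
// term and is ignored, the standard choice for rejection-filtered objectives.
// [[Rcpp::export]]
List cpp_rss_grad(const arma::mat& Z, const arma::vec& dbar, const arma::mat& L,
                  const arma::mat& Bv, const arma::vec& Sobs, double tol,
                  bool want_grad) {
  const arma::uword n = Z.n_rows, N = Bv.n_rows;
  arma::vec acc_sum(N, arma::fill::zeros);
  arma::mat G6(6, N, arma::fill::zeros); // sum_i z_i exp(-d_i . b_j), 6 x N
  arma::uword n_acc = 0;
  const arma::uword blk = 2048;
  const arma::mat Lt = L.t();
  for (arma::uword lo = 0; lo < n; lo += blk) {
    const arma::uword hi = std::min(lo + blk, n) - 1;
    arma::mat Zb = Z.rows(lo, hi);
    arma::mat Db = Zb * Lt;
    Db.each_row() += dbar.t();
    std::vector<arma::uword> keep;
    keep.reserve(Db.n_rows);
    for (arma::uword i = 0; i < Db.n_rows; ++i) {
      double d[6];
      for (int k = 0; k < 6; ++k) d[k] = Db(i, k);
      if (psd6(d, tol)) keep.push_back(i);
    }
    if (keep.empty()) continue;
    arma::uvec kk(keep);
    arma::mat E = arma::exp(-(Db.rows(kk) * Bv.t())); // n_keep x N
    acc_sum += arma::sum(E, 0).t();
    if (want_grad) G6 += Zb.rows(kk).t() * E;
    n_acc += kk.n_elem;
  }
  if (n_acc == 0) {
    return List::create(_["ok"] = false, _["rss"] = R_PosInf,
                        _["acc_frac"] = 0.0);
  }
  arma::vec m = acc_sum / double(n_acc);
  const double mm = arma::dot(m, m);
  const double s0 = mm > 0 ? arma::dot(m, Sobs) / mm : 0.0;
  arma::vec r = Sobs - s0 * m;
  const double rss = arma::dot(r, r);
  List out = List::create(
      _["ok"] = true, _["rss"] = rss, _["s0"] = s0, _["m"] = m,
      _["acc_frac"] = (double)n_acc / (double)n, _["n_acc"] = (double)n_acc);
  if (want_grad) {
    G6 /= double(n_acc);
    arma::vec w = 2.0 * s0 * r; // envelope theorem: s0 held at its optimum
    arma::vec gd = Bv.t() * (w % m);        // d rss / d dbar
    arma::mat H = G6.t();                   // N x 6
    H.each_col() %= w;
    arma::mat gL = Bv.t() * H;              // d rss / d L  (6 x 6)
    out["grad_dbar"] = gd;
    out["grad_L"] = gL;
  }
  return out;
}
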