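// Simulated log-likelihood of the correlated random parameters ordered
// logit, with its analytic gradient.  Parameter vector layout (matching the
// R wrapper crp_theta_*): fixed coefficients (pf), random-coefficient means
// (pr), row-major lower-triangular Cholesky elements (pr*(pr+1)/2), and
// delta = log(psi1).
//
// Per observation i and draw d the random coefficients are b_r + L phi_{id};
// the ordered-logit outcome probability under those coefficients is averaged
// over the D draws before taking logs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List crp_sll_cpp(const arma::vec& theta,
                 const arma::mat& Xf,
                 const arma::mat& Xr,
                 const arma::ivec& y,
                 const arma::cube& Phi,
                 bool want_grad,
                 double floor_eps = 1e-300) {
  const arma::uword n = Xr.n_rows;
  const arma::uword pf = Xf.n_cols;
  const arma::uword pr = Xr.n_cols;
  const arma::uword D = Phi.n_cols;
  const arma::uword nL = pr * (pr + 1) / 2;
  if (theta.n_elem != pf + pr + nL + 1)
    stop("theta length does not match design dimensions");
  if (Phi.n_rows != n || Phi.n_slices != pr)
    stop("draw array does not match design dimensions");

  const arma::vec bf = theta.subvec(0, pf > 0 ? pf - 1 : 0);
  const arma::vec br = theta.subvec(pf, pf + pr - 1);
  arma::mat L(pr, pr, arma::fill::zeros);
  {
    arma::uword pos = pf + pr;
    for (arma::uword j = 0; j < pr; ++j)
      for (arma::uword k = 0; k <= j; ++k)
        L(j, k) = theta(pos++);
  }
  const double psi = std::exp(theta(pf + pr + nL));

  arma::vec base = Xr * br;
  if (pf > 0) base += Xf * bf;
  const arma::mat A = Xr * L;  // n x pr, loading of each phi dimension

  arma::vec S(n, arma::fill::zeros);        // sum over draws of P_id
  arma::vec Weta(n, arma::fill::zeros);     // sum of dP/deta
  arma::vec Wpsi(n, arma::fill::zeros);     // sum of dP/dpsi
  arma::mat G;                              // sum of dP/deta * phi_k
  if (want_grad) G.zeros(n, pr);

  const double epsi = std::exp(-psi);

  // single fused pass per draw; the per-draw slice columns are contiguous
  // and small enough to stay cache-resident.  One exp per element: with
  // e = exp(eta), P(y* <= 0) = 1/(1+e) and P(y* <= psi) = 1/(1+e*exp(-psi));
  // IEEE overflow of e to Inf yields the correct limits 0 and 0.
  std::vector<const double*> phi_col(pr);
  for (arma::uword d = 0; d < D; ++d) {
    for (arma::uword k = 0; k < pr; ++k) phi_col[k] = Phi.slice(k).colptr(d);
    for (arma::uword i = 0; i < n; ++i) {
      double eta = base(i);
      for (arma::uword k = 0; k < pr; ++k) eta += A(i, k) * phi_col[k][i];
      const double e = std::exp(eta);
      const double c0 = 1.0 / (1.0 + e);
      const double c1 = 1.0 / (1.0 + e * epsi);
      const int yi = y(i);
      S(i) += (yi == 0) ? c0 : (yi == 1 ? c1 - c0 : 1.0 - c1);
      if (want_grad) {
        const double f0 = c0 * (1.0 - c0);
        const double f1 = c1 * (1.0 - c1);
        const double dPeta = (yi == 0) ? -f0 : (yi == 1 ? f0 - f1 : f1);
        Weta(i) += dPeta;
        if (yi == 1) Wpsi(i) += f1; else if (yi == 2) Wpsi(i) -= f1;
        for (arma::uword k = 0; k < pr; ++k) G(i, k) += dPeta * phi_col[k][i];
      }
    }
  }

  arma::uvec floored = arma::find(S < floor_eps);
  S.elem(floored).fill(floor_eps);
  const double ll = arma::accu(arma::log(S)) - double(n) * std::log(double(D));

  if (!want_grad)
    return List::create(_["ll"] = ll, _["n_floored"] = (int)floored.n_elem);

  arma::vec grad(theta.n_elem, arma::fill::zeros);
  const arma::vec r = Weta / S;
  if (pf > 0) grad.subvec(0, pf - 1) = Xf.t() * r;
  grad.subvec(pf, pf + pr - 1) = Xr.t() * r;
  {
    arma::mat GS = G.each_col() / S;  // n x pr
    arma::uword pos = pf + pr;
    for (arma::uword j = 0; j < pr; ++j)
      for (arma::uword k = 0; k <= j; ++k)
        grad(pos++) = arma::dot(Xr.col(j), GS.col(k));
  }
  grad(pf + pr + nL) = psi * arma::accu(Wpsi / S);

  return List::create(_["ll"] = ll, _["grad"] = grad,
                      _["n_floored"] = (int)floored.n_elem);
}
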