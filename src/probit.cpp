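// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Probit regression by Fisher scoring (expected-information Newton).
// Returns the coefficient vector, linear predictor, inverse expected
// information (the coefficient covariance), and a convergence flag.
// [[Rcpp::export]]
List probit_irls_cpp(const arma::mat& Z, const arma::vec& s,
                     int max_iter = 30, double tol = 1e-9) {
  int n = Z.n_rows, p = Z.n_cols;
  arma::vec gamma(p, arma::fill::zeros);
  double pbar = arma::mean(s);
  if (pbar <= 0.0 || pbar >= 1.0)
    return List::create(_["converged"] = false);
  gamma[0] = R::qnorm(pbar, 0.0, 1.0, 1, 0);
  arma::vec eta = Z * gamma;
  double dev_old = R_PosInf;
  bool ok = false;
  for (int it = 0; it < max_iter; ++it) {
    arma::vec mu(n), phi(n), w(n), u(n);
    double dev = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = eta[i];
      double P = R::pnorm(e, 0.0, 1.0, 1, 0);
      if (P < 1e-12) P = 1e-12;
      if (P > 1.0 - 1e-12) P = 1.0 - 1e-12;
      double d = R::dnorm(e, 0.0, 1.0, 0);
      mu[i] = P; phi[i] = d;
      double V = P * (1.0 - P);
      w[i] = d * d / V;
      u[i] = d * (s[i] - P) / V;
      dev -= 2.0 * (s[i] > 0.5 ? std::log(P) : std::log(1.0 - P));
    }
    arma::mat H = Z.t() * (Z.each_col() % w);
    arma::vec g = Z.t() * u;
    arma::vec step;
    bool solved = arma::solve(step, H, g, arma::solve_opts::no_approx);
    if (!solved) break;
    gamma += step;
    eta = Z * gamma;
    if (std::abs(dev_old - dev) < tol * (std::abs(dev) + 0.1)) {
      ok = true;
      break;
    }
    dev_old = dev;
  }
  if (!ok || !gamma.is_finite())
    return List::create(_["converged"] = false);
  arma::vec w(n);
  for (int i = 0; i < n; ++i) {
    double e = eta[i];
    double P = R::pnorm(e, 0.0, 1.0, 1, 0);
    if (P < 1e-12) P = 1e-12;
    if (P > 1.0 - 1e-12) P = 1.0 - 1e-12;
    double d = R::dnorm(e, 0.0, 1.0, 0);
    w[i] = d * d / (P * (1.0 - P));
  }
  arma::mat H = Z.t() * (Z.each_col() % w);
  arma::mat Vg;
  if (!arma::inv_sympd(Vg, H))
    return List::create(_["converged"] = false);
  return List::create(_["converged"] = true,
                      _["gamma"] = NumericVector(gamma.begin(), gamma.end()),
                      _["eta"] = NumericVector(eta.begin(), eta.end()),
                      _["Vg"] = wrap(Vg));
}
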