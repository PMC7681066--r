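#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the hierarchical normal meta-analysis model
//   y_i ~ N(theta_i, s2_i)   (s2_i known)
//   theta_i ~ N(mu, tau2)
//   mu ~ N(m0, v0)
//   tau2 ~ InvGamma(a0, b0)
// All full conditionals are conjugate. Uses R's RNG so chains are
// reproducible under set.seed(). If fix_tau2 >= 0 the between-peptide
// variance is held at that value (0 collapses theta_i == mu, giving the
// closed-form conjugate posterior used as a test oracle).
// [[Rcpp::export]]
List gibbs_chain_cpp(NumericVector y, NumericVector s2, int n_keep,
                     int burn_in, double m0, double v0, double a0,
                     double b0, double fix_tau2, double tau2_init) {
  int k = y.size();
  NumericVector theta(k);
  double mu = 0.0;
  double tau2 = (fix_tau2 >= 0.0) ? fix_tau2 : tau2_init;
  NumericVector mu_out(n_keep), tau2_out(n_keep);
  int total = burn_in + n_keep;
  for (int t = 0; t < total; ++t) {
    // theta_i | mu, tau2
    double sum_theta = 0.0, ss = 0.0;
    for (int i = 0; i < k; ++i) {
      if (fix_tau2 == 0.0) {
        theta[i] = mu;
      } else {
        double prec = 1.0 / s2[i] + 1.0 / tau2;
        double mean = (y[i] / s2[i] + mu / tau2) / prec;
        theta[i] = mean + R::rnorm(0.0, 1.0) / std::sqrt(prec);
      }
      sum_theta += theta[i];
    }
    // mu | theta, tau2 (prior N(m0, v0)); when tau2 is fixed at 0 the
    // likelihood term for mu is the peptide-level one directly.
    double prec_mu, mean_mu;
    if (fix_tau2 == 0.0) {
      double py = 0.0, pw = 0.0;
      for (int i = 0; i < k; ++i) { pw += 1.0 / s2[i]; py += y[i] / s2[i]; }
      prec_mu = pw + 1.0 / v0;
      mean_mu = (py + m0 / v0) / prec_mu;
    } else {
      prec_mu = k / tau2 + 1.0 / v0;
      mean_mu = (sum_theta / tau2 + m0 / v0) / prec_mu;
    }
    mu = mean_mu + R::rnorm(0.0, 1.0) / std::sqrt(prec_mu);
    // tau2 | theta, mu
    if (fix_tau2 < 0.0) {
      for (int i = 0; i < k; ++i)
        ss += (theta[i] - mu) * (theta[i] - mu);
      double shape = a0 + 0.5 * k;
      double rate = b0 + 0.5 * ss;
      tau2 = rate / R::rgamma(shape, 1.0);
      if (tau2 < 1e-12) tau2 = 1e-12;
    }
    if (t >= burn_in) {
      mu_out[t - burn_in] = mu;
      tau2_out[t - burn_in] = tau2;
    }
  }
  return List::create(_["mu"] = mu_out, _["tau2"] = tau2_out);
}
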