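#include <Rcpp.h>
#include <cmath>

// Kalman-filter log likelihood for the two-pool LNA bleaching model with
// the quadratic measurement-noise model. Mirrors the R reference
// implementation in R/lna_kalman.R step for step; kept scalar (2-state)
// for speed inside the MCMC sampler.

// [[Rcpp::export]]
double kalman_loglik_cpp(Rcpp::NumericVector y, Rcpp::NumericVector times,
                         double lambda1, double lambda2, double x10,
                         double x20, double f, double nu, double s0,
                         double s1, double s2, bool clip = true) {
  const int n = y.size();
  if (n < 1 || times.size() != n) Rcpp::stop("length mismatch");

  double mu1 = x10, mu2 = x20;
  double S11 = 0.0, S22 = 0.0, S12 = 0.0;
  const double log2pi = std::log(2.0 * M_PI);
  double loglik = 0.0;

  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      const double dt = times[i] - times[i - 1];
      const double l1 = std::exp(-lambda1 * dt);
      const double l2 = std::exp(-lambda2 * dt);
      S11 = S11 * l1 * l1 + l1 * (1.0 - l1) * mu1;
      S22 = S22 * l2 * l2 + l2 * (1.0 - l2) * mu2;
      S12 = S12 * l1 * l2;
      mu1 *= l1;
      mu2 *= l2;
    }
    const double s = nu * (mu1 + mu2);
    const double USU = nu * nu * (S11 + 2.0 * S12 + S22);
    // state-dependent noise variance from the predicted state
    const double V = s0 * s0 + s * s1 * s1 + (s * s + USU) * s2 * s2;
    if (!(V > 0.0)) return -INFINITY;
    const double pv = USU + V;  // predictive variance of y_i
    if (!(pv > 0.0) || !std::isfinite(pv)) return -INFINITY;
    const double r = (y[i] - f) - s;
    loglik += -0.5 * (log2pi + std::log(pv) + r * r / pv);

    // measurement update (Joseph form reduces to this scalar algebra)
    const double K1 = nu * (S11 + S12) / pv;
    const double K2 = nu * (S12 + S22) / pv;
    mu1 += K1 * r;
    mu2 += K2 * r;
    if (clip) {
      if (mu1 < 0.0) mu1 = 0.0;
      if (mu2 < 0.0) mu2 = 0.0;
    }
    const double S11n = S11 - K1 * nu * (S11 + S12);
    const double S22n = S22 - K2 * nu * (S12 + S22);
    const double S12n = S12 - K1 * nu * (S12 + S22);
    S11 = S11n;
    S22 = S22n;
    S12 = S12n;
    if (S11 < 0.0) S11 = 0.0;
    if (S22 < 0.0) S22 = 0.0;
  }
  return loglik;
}
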