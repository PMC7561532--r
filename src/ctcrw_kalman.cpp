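#include <Rcpp.h>
using namespace Rcpp;

// Kalman-filter log-likelihood of the integrated Ornstein-Uhlenbeck
// (CTCRW) model for one coordinate axis. times in hours, z in meters
// (NA = missing slot, predict only). sigma is the stationary velocity
// SD (m/h), beta the velocity autocorrelation rate (1/h), tau the
// measurement noise SD (m).
// [[Rcpp::export(name = ".ctcrw_loglik_cpp")]]
double ctcrw_loglik_cpp(NumericVector times, NumericVector z, double beta,
                        double sigma, double tau, double prior_mean,
                        double prior_var) {
  const int n = times.size();
  double m0 = prior_mean, m1 = 0.0;
  double P00 = prior_var, P01 = 0.0, P11 = sigma * sigma;
  double ll = 0.0;
  for (int k = 0; k < n; ++k) {
    if (k > 0) {
      const double dt = times[k] - times[k - 1];
      const double phi = std::exp(-beta * dt);
      const double f01 = (1.0 - phi) / beta;
      const double q00 = sigma * sigma / (beta * beta) *
        (2.0 * beta * dt - 3.0 + 4.0 * phi - phi * phi);
      const double q01 = sigma * sigma / beta * (1.0 - phi) * (1.0 - phi);
      const double q11 = sigma * sigma * (1.0 - phi * phi);
      const double nm0 = m0 + f01 * m1;
      const double nm1 = phi * m1;
      const double nP00 = P00 + 2.0 * f01 * P01 + f01 * f01 * P11 + q00;
      const double nP01 = phi * (P01 + f01 * P11) + q01;
      const double nP11 = phi * phi * P11 + q11;
      m0 = nm0; m1 = nm1; P00 = nP00; P01 = nP01; P11 = nP11;
    }
    if (!NumericVector::is_na(z[k])) {
      const double S = P00 + tau * tau;
      const double v = z[k] - m0;
      ll += -0.5 * (std::log(2.0 * M_PI * S) + v * v / S);
      const double K0 = P00 / S, K1 = P01 / S;
      m0 += K0 * v; m1 += K1 * v;
      const double nP00 = P00 - K0 * P00;
      const double nP01 = P01 - K0 * P01;
      const double nP11 = P11 - K1 * P01;
      P00 = nP00; P01 = nP01; P11 = nP11;
    }
  }
  return ll;
}
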