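#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-algorithm log-likelihood for one observation sequence.
// logB: T x N matrix of per-step log emission densities (rows with all
// zeros are fully missing observations and contribute transitions only).
// Gamma: N x N transition matrix; delta: initial distribution.
// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(NumericMatrix logB, NumericMatrix Gamma,
                       NumericVector delta) {
  const int T = logB.nrow(), N = logB.ncol();
  std::vector<double> alpha(N), tmp(N);
  double ll = 0.0;

  // first step
  double m = R_NegInf;
  for (int j = 0; j < N; ++j) m = std::max(m, logB(0, j));
  if (!R_finite(m)) m = 0.0;
  double s = 0.0;
  for (int j = 0; j < N; ++j) {
    alpha[j] = delta[j] * std::exp(logB(0, j) - m);
    s += alpha[j];
  }
  if (s <= 0.0) return R_NegInf;
  for (int j = 0; j < N; ++j) alpha[j] /= s;
  ll += std::log(s) + m;

  for (int t = 1; t < T; ++t) {
    m = R_NegInf;
    for (int j = 0; j < N; ++j) m = std::max(m, logB(t, j));
    if (!R_finite(m)) m = 0.0;
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double a = 0.0;
      for (int i = 0; i < N; ++i) a += alpha[i] * Gamma(i, j);
      tmp[j] = a * std::exp(logB(t, j) - m);
      s += tmp[j];
    }
    if (s <= 0.0) return R_NegInf;
    for (int j = 0; j < N; ++j) alpha[j] = tmp[j] / s;
    ll += std::log(s) + m;
  }
  return ll;
}
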