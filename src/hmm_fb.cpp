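#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass: returns the log-likelihood, smoothing
// probabilities gamma (T x N), summed expected transition counts
// xi (N x N), and gamma at t = 1. Shares the emission conventions of
// the forward routine (all-zero logB rows are missing observations).
// [[Rcpp::export(name = ".hmm_fb_cpp")]]
List hmm_fb_cpp(NumericMatrix logB, NumericMatrix Gamma,
                NumericVector delta) {
  const int T = logB.nrow(), N = logB.ncol();
  NumericMatrix alpha(T, N), beta(T, N), B(T, N), post(T, N);
  NumericVector cvec(T), rowmax(T);
  double ll = 0.0;

  for (int t = 0; t < T; ++t) {
    double m = R_NegInf;
    for (int j = 0; j < N; ++j) m = std::max(m, logB(t, j));
    if (!R_finite(m)) m = 0.0;
    rowmax[t] = m;
    for (int j = 0; j < N; ++j) B(t, j) = std::exp(logB(t, j) - m);
  }

  double s = 0.0;
  for (int j = 0; j < N; ++j) { alpha(0, j) = delta[j] * B(0, j); s += alpha(0, j); }
  if (s <= 0.0) return List::create(Named("loglik") = R_NegInf);
  for (int j = 0; j < N; ++j) alpha(0, j) /= s;
  cvec[0] = s; ll += std::log(s) + rowmax[0];

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double a = 0.0;
      for (int i = 0; i < N; ++i) a += alpha(t - 1, i) * Gamma(i, j);
      alpha(t, j) = a * B(t, j);
      s += alpha(t, j);
    }
    if (s <= 0.0) return List::create(Named("loglik") = R_NegInf);
    for (int j = 0; j < N; ++j) alpha(t, j) /= s;
    cvec[t] = s; ll += std::log(s) + rowmax[t];
  }

  for (int j = 0; j < N; ++j) beta(T - 1, j) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < N; ++i) {
      double b = 0.0;
      for (int j = 0; j < N; ++j) b += Gamma(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / cvec[t + 1];
    }
  }

  NumericMatrix xi(N, N);
  for (int t = 0; t < T; ++t) {
    double ps = 0.0;
    for (int j = 0; j < N; ++j) { post(t, j) = alpha(t, j) * beta(t, j); ps += post(t, j); }
    for (int j = 0; j < N; ++j) post(t, j) /= ps;
  }
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < N; ++j) {
        xi(i, j) += alpha(t - 1, i) * Gamma(i, j) * B(t, j) * beta(t, j) /
          cvec[t];
      }
    }
  }

  return List::create(Named("loglik") = ll, Named("post") = post,
                      Named("xi") = xi,
                      Named("post1") = post(0, _));
}
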