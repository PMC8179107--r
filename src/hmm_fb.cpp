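#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward E-step for a discrete-output HMM.
// obs: 1-based observation symbols; A: n x n hidden transitions;
// B: n x m emission probabilities; pi0: initial hidden distribution.
// Returns the log-likelihood and the expected sufficient statistics
// (transition counts, emission counts, initial-state posterior).
// [[Rcpp::export]]
List hmm_forward_backward(IntegerVector obs, NumericMatrix A,
                          NumericMatrix B, NumericVector pi0) {
  const int T = obs.size();
  const int n = A.nrow();
  const int m = B.ncol();
  NumericMatrix alpha(T, n), beta(T, n);
  NumericVector scale(T);
  double loglik = 0.0;

  // forward with per-step scaling
  {
    int o = obs[0] - 1;
    double s = 0.0;
    for (int i = 0; i < n; ++i) { alpha(0, i) = pi0[i] * B(i, o); s += alpha(0, i); }
    if (s <= 0) s = 1e-300;
    for (int i = 0; i < n; ++i) alpha(0, i) /= s;
    scale[0] = s; loglik += std::log(s);
  }
  for (int t = 1; t < T; ++t) {
    int o = obs[t] - 1;
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      double a = 0.0;
      for (int i = 0; i < n; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= B(j, o);
      alpha(t, j) = a; s += a;
    }
    if (s <= 0) s = 1e-300;
    for (int j = 0; j < n; ++j) alpha(t, j) /= s;
    scale[t] = s; loglik += std::log(s);
  }

  // backward, same scaling
  for (int i = 0; i < n; ++i) beta(T - 1, i) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    int o = obs[t + 1] - 1;
    for (int i = 0; i < n; ++i) {
      double b = 0.0;
      for (int j = 0; j < n; ++j) b += A(i, j) * B(j, o) * beta(t + 1, j);
      beta(t, i) = b / scale[t + 1];
    }
  }

  NumericMatrix xi_sum(n, n), gamma_obs(n, m);
  NumericVector gamma0(n);
  for (int t = 0; t < T; ++t) {
    double norm = 0.0;
    for (int i = 0; i < n; ++i) norm += alpha(t, i) * beta(t, i);
    if (norm <= 0) norm = 1e-300;
    int o = obs[t] - 1;
    for (int i = 0; i < n; ++i) {
      double g = alpha(t, i) * beta(t, i) / norm;
      gamma_obs(i, o) += g;
      if (t == 0) gamma0[i] = g;
    }
  }
  for (int t = 0; t < T - 1; ++t) {
    int o = obs[t + 1] - 1;
    double norm = 0.0;
    NumericMatrix xi(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double v = alpha(t, i) * A(i, j) * B(j, o) * beta(t + 1, j);
        xi(i, j) = v; norm += v;
      }
    if (norm <= 0) norm = 1e-300;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) xi_sum(i, j) += xi(i, j) / norm;
  }

  return List::create(_["loglik"] = loglik, _["xi_sum"] = xi_sum,
                      _["gamma_obs"] = gamma_obs, _["gamma0"] = gamma0);
}
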