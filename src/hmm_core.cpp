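#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a discrete-state HMM.
// B: T x K matrix of per-frame emission densities (linear scale),
// A: K x K transition matrix, pi: initial distribution.
// Returns log-likelihood, smoothed state posteriors (gamma) and the
// summed two-slice posteriors (xi) needed for the EM transition update.
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix B, NumericMatrix A, NumericVector pi) {
  const int T = B.nrow(), K = B.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector c(T);

  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0.0) s = 1e-300;
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= B(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0.0) s = 1e-300;
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / c[t + 1];
    }
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    if (g > 0.0) for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; ++t) {
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) {
        xi(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / c[t + 1];
      }
    }
  }

  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi maximum a posteriori path on the log scale. Ties are broken
// toward the lower state index (states are ordered by ascending mean,
// so this realises the documented lower-mean tie rule).
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logB, NumericMatrix logA, NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);

  for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }  // strict ">" keeps lowest index on ties
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }

  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k) {
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);

  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based state labels
  return path;
}
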