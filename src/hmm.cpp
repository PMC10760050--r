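#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One forward-backward pass for a Bernoulli-emission HMM with scaling.
// x: 0/1 observations; e: per-state P(x=1); A: K x K transitions; pi: init.
// Returns sufficient statistics for one EM update plus the log-likelihood.
// [[Rcpp::export]]
List fb_bernoulli(IntegerVector x, NumericVector e, NumericMatrix A,
                  NumericVector pi) {
  const int T = x.size(), K = e.size();
  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector scale(T), gamma0(K), gamma_sum(K), gamma_x_sum(K);
  NumericMatrix xi_sum(K, K);

  auto emit = [&](int t, int k) {
    return x[t] == 1 ? e[k] : 1.0 - e[k];
  };

  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * emit(0, k); s += alpha(0, k); }
  if (s <= 0) stop("zero forward probability at t=0");
  scale[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = a * emit(t, k);
      s += alpha(t, k);
    }
    if (s <= 0) stop("zero forward probability");
    scale[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(k, j) * emit(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / scale[t + 1];
    }
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(scale[t]);

  for (int t = 0; t < T; ++t) {
    double norm = 0.0;
    for (int k = 0; k < K; ++k) norm += alpha(t, k) * beta(t, k);
    for (int k = 0; k < K; ++k) {
      double g = alpha(t, k) * beta(t, k) / norm;
      if (t == 0) gamma0[k] = g;
      gamma_sum[k] += g;
      if (x[t] == 1) gamma_x_sum[k] += g;
    }
  }

  for (int t = 0; t < T - 1; ++t) {
    double norm = 0.0;
    NumericMatrix tmp(K, K);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) {
        tmp(j, k) = alpha(t, j) * A(j, k) * emit(t + 1, k) * beta(t + 1, k);
        norm += tmp(j, k);
      }
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) xi_sum(j, k) += tmp(j, k) / norm;
  }

  return List::create(_["loglik"] = loglik, _["gamma0"] = gamma0,
                      _["gamma_sum"] = gamma_sum,
                      _["gamma_x_sum"] = gamma_x_sum, _["xi_sum"] = xi_sum);
}

// Most probable state path (Viterbi), 1-based states.
// [[Rcpp::export]]
IntegerVector viterbi_bernoulli(IntegerVector x, NumericVector e,
                                NumericMatrix A, NumericVector pi) {
  const int T = x.size(), K = e.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  const double NEG = -1e300;

  auto lemit = [&](int t, int k) {
    double p = x[t] == 1 ? e[k] : 1.0 - e[k];
    return p > 0 ? std::log(p) : NEG;
  };
  NumericMatrix lA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      lA(j, k) = A(j, k) > 0 ? std::log(A(j, k)) : NEG;

  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi[k] > 0 ? std::log(pi[k]) : NEG) + lemit(0, k);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = NEG * 2; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + lA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + lemit(t, k);
      psi(t, k) = arg;
    }

  IntegerVector path(T);
  int arg = 0; double best = NEG * 2;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
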