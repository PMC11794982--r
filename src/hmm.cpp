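#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-state Gaussian HMM primitives. Everything is done in log space so
// that near-degenerate emission variances (e.g. an untranscribed state
// pinned to all-zero bins) cannot underflow the forward recursion.

static inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = (a > b) ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Forward-backward pass for one observation sequence.
// logB is T x 2 (per-bin emission log density under each state).
// Returns the sequence log-likelihood, posterior state probabilities
// gamma (T x 2), summed transition posteriors xi_sum (2 x 2), and the
// t = 1 posterior used for the initial-distribution update.
// [[Rcpp::export]]
List hmm_fb_cpp(NumericVector logpi, NumericMatrix logA, NumericMatrix logB) {
  const int T = logB.nrow();
  NumericMatrix la(T, 2), lb(T, 2), gamma(T, 2);
  NumericMatrix xi(2, 2);
  std::fill(xi.begin(), xi.end(), 0.0);

  la(0, 0) = logpi[0] + logB(0, 0);
  la(0, 1) = logpi[1] + logB(0, 1);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < 2; ++j)
      la(t, j) = logsumexp2(la(t - 1, 0) + logA(0, j),
                            la(t - 1, 1) + logA(1, j)) + logB(t, j);

  lb(T - 1, 0) = 0.0;
  lb(T - 1, 1) = 0.0;
  for (int t = T - 2; t >= 0; --t)
    for (int i = 0; i < 2; ++i)
      lb(t, i) = logsumexp2(logA(i, 0) + logB(t + 1, 0) + lb(t + 1, 0),
                            logA(i, 1) + logB(t + 1, 1) + lb(t + 1, 1));

  const double ll = logsumexp2(la(T - 1, 0), la(T - 1, 1));

  for (int t = 0; t < T; ++t) {
    double g0 = la(t, 0) + lb(t, 0) - ll;
    double g1 = la(t, 1) + lb(t, 1) - ll;
    gamma(t, 0) = std::exp(g0);
    gamma(t, 1) = std::exp(g1);
  }

  for (int t = 0; t < T - 1; ++t)
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j)
        xi(i, j) += std::exp(la(t, i) + logA(i, j) + logB(t + 1, j) +
                             lb(t + 1, j) - ll);

  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["xi_sum"] = xi);
}

// Viterbi decoding. Ties are broken toward state 0 (untranscribed) both
// in the per-step predecessor choice and in the terminal argmax; the
// decoded path is therefore the maximising path whose states are
// minimal from the last bin backwards.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector logpi, NumericMatrix logA,
                              NumericMatrix logB) {
  const int T = logB.nrow();
  NumericVector d0(T), d1(T);
  IntegerVector psi0(T), psi1(T), path(T);

  d0[0] = logpi[0] + logB(0, 0);
  d1[0] = logpi[1] + logB(0, 1);
  for (int t = 1; t < T; ++t) {
    double a0 = d0[t - 1] + logA(0, 0), b0 = d1[t - 1] + logA(1, 0);
    psi0[t] = (b0 > a0) ? 1 : 0;
    d0[t] = ((b0 > a0) ? b0 : a0) + logB(t, 0);
    double a1 = d0[t - 1] + logA(0, 1), b1 = d1[t - 1] + logA(1, 1);
    psi1[t] = (b1 > a1) ? 1 : 0;
    d1[t] = ((b1 > a1) ? b1 : a1) + logB(t, 1);
  }

  path[T - 1] = (d1[T - 1] > d0[T - 1]) ? 1 : 0;
  for (int t = T - 2; t >= 0; --t)
    path[t] = (path[t + 1] == 0) ? psi0[t + 1] : psi1[t + 1];
  return path;
}
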