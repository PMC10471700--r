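// Scaled forward-backward, Baum-Welch and Viterbi kernels for a
// Bernoulli-emission HMM over a binarized mark track. Scaling constants
// carry the log-likelihood, so no underflow at genome scale.
#include <Rcpp.h>
using namespace Rcpp;

// emission probability of observation x (0/1) in state s
static inline double emit(int x, double e) { return x ? e : 1.0 - e; }

// [[Rcpp::export]]
List hmm_forward_cpp(IntegerVector x, NumericVector pi, NumericMatrix A,
                     NumericVector e) {
  const int n = x.size(), S = pi.size();
  NumericMatrix alpha(n, S);
  NumericVector c(n);
  double ll = 0.0;
  for (int s = 0; s < S; ++s) alpha(0, s) = pi[s] * emit(x[0], e[s]);
  double z = 0.0;
  for (int s = 0; s < S; ++s) z += alpha(0, s);
  c[0] = z;
  for (int s = 0; s < S; ++s) alpha(0, s) /= z;
  ll += std::log(z);
  for (int t = 1; t < n; ++t) {
    z = 0.0;
    for (int s = 0; s < S; ++s) {
      double acc = 0.0;
      for (int r = 0; r < S; ++r) acc += alpha(t - 1, r) * A(r, s);
      alpha(t, s) = acc * emit(x[t], e[s]);
      z += alpha(t, s);
    }
    c[t] = z;
    for (int s = 0; s < S; ++s) alpha(t, s) /= z;
    ll += std::log(z);
  }
  return List::create(_["alpha"] = alpha, _["scale"] = c, _["loglik"] = ll);
}

// [[Rcpp::export]]
double hmm_loglik_backward_cpp(IntegerVector x, NumericVector pi,
                               NumericMatrix A, NumericVector e) {
  const int n = x.size(), S = pi.size();
  std::vector<double> beta(S, 1.0), nb(S);
  double ll = 0.0;
  for (int t = n - 1; t >= 1; --t) {
    double z = 0.0;
    for (int r = 0; r < S; ++r) {
      double acc = 0.0;
      for (int s = 0; s < S; ++s) acc += A(r, s) * emit(x[t], e[s]) * beta[s];
      nb[r] = acc;
      z += acc;
    }
    for (int r = 0; r < S; ++r) beta[r] = nb[r] / (z / S);
    ll += std::log(z / S);
  }
  double z0 = 0.0;
  for (int s = 0; s < S; ++s) z0 += pi[s] * emit(x[0], e[s]) * beta[s];
  return ll + std::log(z0);
}

// One Baum-Welch run from a given start; returns the fitted model and the
// per-iteration log-likelihood trace (nondecreasing up to round-off).
// [[Rcpp::export]]
List hmm_baum_welch_cpp(IntegerVector x, NumericVector pi0, NumericMatrix A0,
                        NumericVector e0, double tol, int max_iter) {
  const int n = x.size(), S = pi0.size();
  NumericVector pi = clone(pi0), e = clone(e0);
  NumericMatrix A = clone(A0);
  NumericMatrix alpha(n, S), beta(n, S);
  NumericVector c(n);
  std::vector<double> trace;
  double prev_ll = R_NegInf, ll = R_NegInf;
  for (int it = 0; it < max_iter; ++it) {
    // forward (scaled)
    ll = 0.0;
    double z = 0.0;
    for (int s = 0; s < S; ++s) { alpha(0, s) = pi[s] * emit(x[0], e[s]); z += alpha(0, s); }
    c[0] = z; ll += std::log(z);
    for (int s = 0; s < S; ++s) alpha(0, s) /= z;
    for (int t = 1; t < n; ++t) {
      z = 0.0;
      for (int s = 0; s < S; ++s) {
        double acc = 0.0;
        for (int r = 0; r < S; ++r) acc += alpha(t - 1, r) * A(r, s);
        alpha(t, s) = acc * emit(x[t], e[s]);
        z += alpha(t, s);
      }
      c[t] = z; ll += std::log(z);
      for (int s = 0; s < S; ++s) alpha(t, s) /= z;
    }
    trace.push_back(ll);
    // backward (same scaling)
    for (int s = 0; s < S; ++s) beta(n - 1, s) = 1.0;
    for (int t = n - 2; t >= 0; --t) {
      for (int r = 0; r < S; ++r) {
        double acc = 0.0;
        for (int s = 0; s < S; ++s) acc += A(r, s) * emit(x[t + 1], e[s]) * beta(t + 1, s);
        beta(t, r) = acc / c[t + 1];
      }
    }
    // E step accumulators / M step
    std::vector<double> gsum(S, 0.0), gsum1(S, 0.0), esum(S, 0.0), pin(S, 0.0);
    NumericMatrix xisum(S, S);
    for (int t = 0; t < n; ++t) {
      for (int s = 0; s < S; ++s) {
        double g = alpha(t, s) * beta(t, s);
        if (t == 0) pin[s] = g;
        gsum[s] += g;
        if (x[t]) esum[s] += g;
        if (t < n - 1) gsum1[s] += g;
      }
    }
    for (int t = 0; t < n - 1; ++t)
      for (int r = 0; r < S; ++r)
        for (int s = 0; s < S; ++s)
          xisum(r, s) += alpha(t, r) * A(r, s) * emit(x[t + 1], e[s]) *
                         beta(t + 1, s) / c[t + 1];
    for (int s = 0; s < S; ++s) {
      pi[s] = pin[s];
      e[s] = gsum[s] > 0 ? esum[s] / gsum[s] : 0.5;
      // clamp away from the boundary so emissions stay proper probabilities
      if (e[s] < 1e-8) e[s] = 1e-8;
      if (e[s] > 1 - 1e-8) e[s] = 1 - 1e-8;
    }
    for (int r = 0; r < S; ++r) {
      double rs = 0.0;
      for (int s = 0; s < S; ++s) rs += xisum(r, s);
      for (int s = 0; s < S; ++s)
        A(r, s) = rs > 0 ? xisum(r, s) / rs : 1.0 / S;
    }
    if (it > 0 && std::abs(ll - prev_ll) < tol * (1.0 + std::abs(ll))) break;
    prev_ll = ll;
  }
  return List::create(_["pi"] = pi, _["A"] = A, _["e"] = e,
                      _["loglik"] = ll, _["trace"] = wrap(trace));
}

// Viterbi decoding; score ties resolved toward the lowest state index.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(IntegerVector x, NumericVector pi,
                              NumericMatrix A, NumericVector e) {
  const int n = x.size(), S = pi.size();
  NumericMatrix d(n, S);
  IntegerMatrix bp(n, S);
  const double NEG = -1e300;
  for (int s = 0; s < S; ++s) {
    double le = std::log(emit(x[0], e[s]));
    d(0, s) = (pi[s] > 0 ? std::log(pi[s]) : NEG) + le;
  }
  for (int t = 1; t < n; ++t)
    for (int s = 0; s < S; ++s) {
      double best = NEG * 2; int arg = 0;
      for (int r = 0; r < S; ++r) {
        double v = d(t - 1, r) + (A(r, s) > 0 ? std::log(A(r, s)) : NEG);
        if (v > best) { best = v; arg = r; } // strict >: ties keep lowest r
      }
      d(t, s) = best + std::log(emit(x[t], e[s]));
      bp(t, s) = arg;
    }
  IntegerVector path(n);
  double best = NEG * 2; int arg = 0;
  for (int s = 0; s < S; ++s) if (d(n - 1, s) > best) { best = d(n - 1, s); arg = s; }
  path[n - 1] = arg;
  for (int t = n - 1; t >= 1; --t) path[t - 1] = bp(t, path[t]);
  return path + 1; // 1-based state indices for R
}
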