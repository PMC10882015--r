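#include <Rcpp.h>
using namespace Rcpp;

// Scaled variance of the Mann-Kendall S statistic under long-term
// persistence: sum over all pairs of pairs (i<j), (k<l) of
// (2/pi) * asin( (rho|j-l| - rho|i-l| - rho|j-k| + rho|i-k|)
//                / sqrt((2 - 2 rho|i-j|)(2 - 2 rho|k-l|)) ),
// with rho the fGn autocorrelation at the estimated Hurst exponent.
// tpos are the (1-based or 0-based, only differences matter) time
// positions of the observed values, so series with missing years are
// handled by their true spacing. rho must cover lags 0..max diff.
// [[Rcpp::export]]
double mmk_varH_cpp(NumericVector rho, IntegerVector tpos) {
  int n = tpos.size();
  int m = n * (n - 1) / 2;
  std::vector<int> pi_(m), pj_(m);
  int c = 0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      pi_[c] = tpos[i];
      pj_[c] = tpos[j];
      ++c;
    }
  double total = 0.0;
  const double two_over_pi = 2.0 / M_PI;
  for (int p = 0; p < m; ++p) {
    int i = pi_[p], j = pj_[p];
    double dp = 2.0 - 2.0 * rho[std::abs(j - i)];
    for (int q = p; q < m; ++q) {
      int k = pi_[q], l = pj_[q];
      double dq = 2.0 - 2.0 * rho[std::abs(l - k)];
      double num = rho[std::abs(j - l)] - rho[std::abs(i - l)]
                 - rho[std::abs(j - k)] + rho[std::abs(i - k)];
      double den = std::sqrt(dp * dq);
      double arg = (den > 0) ? num / den : 0.0;
      if (arg > 1.0) arg = 1.0;
      if (arg < -1.0) arg = -1.0;
      double term = two_over_pi * std::asin(arg);
      total += (q == p) ? term : 2.0 * term;
    }
  }
  return total;
}

// Exact Gaussian log-likelihood pieces for a stationary series with
// Toeplitz correlation given by r (lags 0..n-1, r[0] = 1), via the
// Levinson-Durbin recursion: returns log|C| and the quadratic form
// z' C^{-1} z in O(n^2) without forming C.
// [[Rcpp::export]]
NumericVector toeplitz_loglik_parts_cpp(NumericVector r, NumericVector z) {
  int n = z.size();
  std::vector<double> phi(n, 0.0), phi_old(n, 0.0);
  double v = 1.0;          // innovation variance, order 0
  double logdet = 0.0;     // log prod v_k, v_0 = 1
  double e = z[0];
  double quad = e * e;     // e_0^2 / v_0
  for (int k = 1; k < n; ++k) {
    double alpha = r[k];
    for (int j = 1; j < k; ++j) alpha -= phi[j] * r[k - j];
    double refl = alpha / v;
    for (int j = 1; j < k; ++j) phi_old[j] = phi[j];
    for (int j = 1; j < k; ++j) phi[j] = phi_old[j] - refl * phi_old[k - j];
    phi[k] = refl;
    v *= (1.0 - refl * refl);
    if (v <= 0) {
      // correlation sequence numerically non-positive-definite
      return NumericVector::create(NA_REAL, NA_REAL);
    }
    logdet += std::log(v);
    e = z[k];
    for (int j = 1; j <= k; ++j) e -= phi[j] * z[k - j];
    quad += e * e / v;
  }
  return NumericVector::create(logdet, quad);
}
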