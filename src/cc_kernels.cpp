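#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pearson correlation of x against y shifted by each lag in [-max_lag,
// max_lag], normalized over the overlapping region only. Positive lag L
// pairs x[i] with y[i + L] (x leads y). Degenerate overlaps (variance 0 or
// fewer than 2 samples) yield r = 0 and a flag.
static void pearson_lags(const double* x, const double* y, int n, int max_lag,
                         double* r, int* degen) {
  for (int L = -max_lag; L <= max_lag; ++L) {
    const double* a = x;
    const double* b = y;
    int lag = L;
    if (L < 0) { a = y; b = x; lag = -L; }
    int m = n - lag;
    int idx = L + max_lag;
    if (m < 2) { r[idx] = 0.0; degen[idx] = 1; continue; }
    double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    for (int i = 0; i < m; ++i) {
      double xa = a[i], yb = b[i + lag];
      sx += xa; sy += yb;
      sxx += xa * xa; syy += yb * yb; sxy += xa * yb;
    }
    double vx = sxx - sx * sx / m;
    double vy = syy - sy * sy / m;
    if (vx <= 0.0 || vy <= 0.0) {
      r[idx] = 0.0; degen[idx] = 1;
    } else {
      r[idx] = (sxy - sx * sy / m) / std::sqrt(vx * vy);
      degen[idx] = 0;
    }
  }
}

// [[Rcpp::export]]
List cc_lags_cpp(NumericVector x, NumericVector y, int max_lag) {
  int n = x.size();
  if (y.size() != n) stop("length mismatch");
  if (max_lag < 0) stop("max_lag must be >= 0");
  int nl = 2 * max_lag + 1;
  NumericVector r(nl);
  IntegerVector degen(nl);
  pearson_lags(REAL(x), REAL(y), n, max_lag, REAL(r), INTEGER(degen));
  return List::create(_["r"] = r, _["degenerate"] = degen);
}

// Jitter-surrogate null for the lagged correlation of one electrode pair.
// y spike times are displaced by U(-jitter, jitter) with circular wrap at
// the recording boundaries, re-binned, and correlated against the fixed
// binned x. Exceedance counts against the observed central-bin and
// maximum-bin coefficients give sequential Monte-Carlo p-values
// (Besag-Clifford): stop once both counts reach m_stop (p = count/draws),
// otherwise p = (count + 1) / (n_surr + 1). Uses R's RNG.
// [[Rcpp::export]]
List surrogate_pvals_cpp(NumericVector x, NumericVector y_times, double bin_s,
                         int n_bins, int max_lag, double jitter_s,
                         double duration_s, int n_surr, int m_stop,
                         double obs_c0, double obs_cmax) {
  if (x.size() != n_bins) stop("x must have n_bins entries");
  int nl = 2 * max_lag + 1;
  std::vector<double> yb(n_bins), r(nl);
  std::vector<int> degen(nl);
  int ny = y_times.size();
  int count0 = 0, countm = 0, done = 0;
  for (int s = 0; s < n_surr; ++s) {
    std::fill(yb.begin(), yb.end(), 0.0);
    for (int i = 0; i < ny; ++i) {
      double t = y_times[i] + R::runif(-jitter_s, jitter_s);
      t -= duration_s * std::floor(t / duration_s);  // circular wrap
      if (t >= duration_s) t = 0.0;
      int b = (int)(t / bin_s);
      if (b >= n_bins) b = n_bins - 1;
      yb[b] += 1.0;
    }
    pearson_lags(REAL(x), yb.data(), n_bins, max_lag, r.data(), degen.data());
    double c0 = r[max_lag];
    double cmax = r[0];
    for (int k = 1; k < nl; ++k) if (r[k] > cmax) cmax = r[k];
    if (c0 >= obs_c0) ++count0;
    if (cmax >= obs_cmax) ++countm;
    ++done;
    if (count0 >= m_stop && countm >= m_stop) break;
  }
  double p0 = (count0 >= m_stop) ? (double)count0 / done
                                 : (count0 + 1.0) / (n_surr + 1.0);
  double pm = (countm >= m_stop) ? (double)countm / done
                                 : (countm + 1.0) / (n_surr + 1.0);
  return List::create(_["p_c0"] = p0, _["p_cmax"] = pm,
                      _["n_surrogates_used"] = done);
}
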