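#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shift the IRF by `shift` bins (continuous; linear interpolation, zero
// outside the recorded window). Positive shift moves the IRF later in time.
static std::vector<double> shift_irf(const NumericVector& irf, double shift) {
  const int n = irf.size();
  std::vector<double> out(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const double pos = i - shift;          // sample original IRF at i - shift
    const int k = (int)std::floor(pos);
    const double f = pos - k;
    double v = 0.0;
    if (k >= 0 && k < n)       v += (1.0 - f) * irf[k];
    if (k + 1 >= 0 && k + 1 < n) v += f * irf[k + 1];
    out[i] = v;
  }
  return out;
}

// Expected bin counts for the IRF-convolved two-component decay model:
//   m_i = N * [ (1 - bg) * (IRF (*) decay)_i / sum + bg / n_bins ]
// theta = (alpha1 [%], tau1 [ns], tau2 [ns], bg [fraction], shift [bins]).
// [[Rcpp::export(rng = false)]]
NumericVector cpp_decay_model(NumericVector theta, NumericVector irf,
                              double dt, double total_counts) {
  const int n = irf.size();
  const double alpha1 = theta[0] / 100.0, tau1 = theta[1], tau2 = theta[2];
  const double bg = theta[3], shift = theta[4];
  const double alpha2 = 1.0 - alpha1;

  std::vector<double> irfs = shift_irf(irf, shift);
  int jmin = 0, jmax = n - 1;
  while (jmin < n && irfs[jmin] <= 0.0) ++jmin;
  while (jmax >= 0 && irfs[jmax] <= 0.0) --jmax;

  std::vector<double> d(n);
  const double e1 = std::exp(-dt / tau1), e2 = std::exp(-dt / tau2);
  double v1 = std::exp(-0.5 * dt / tau1) / tau1 * alpha1;
  double v2 = std::exp(-0.5 * dt / tau2) / tau2 * alpha2;
  for (int i = 0; i < n; ++i) {
    d[i] = v1 + v2;
    v1 *= e1;
    v2 *= e2;
  }

  NumericVector m(n);
  double conv_sum = 0.0;
  for (int i = 0; i < n; ++i) {
    double c = 0.0;
    const int jhi = std::min(i, jmax);
    for (int j = jmin; j <= jhi; ++j) c += irfs[j] * d[i - j];
    m[i] = c;
    conv_sum += c;
  }
  if (conv_sum <= 0.0) {
    for (int i = 0; i < n; ++i) m[i] = total_counts / n;
    return m;
  }
  for (int i = 0; i < n; ++i)
    m[i] = total_counts * ((1.0 - bg) * m[i] / conv_sum + bg / n);
  return m;
}

// Fit objective. poisson = true: Poisson negative log-likelihood (up to the
// data-only constant); otherwise Neyman-weighted least squares with weights
// 1/max(counts, 1).
// [[Rcpp::export(rng = false)]]
double cpp_decay_objective(NumericVector theta, NumericVector counts,
                           NumericVector irf, double dt, bool poisson) {
  const int n = counts.size();
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += counts[i];
  NumericVector m = cpp_decay_model(theta, irf, dt, total);
  double obj = 0.0;
  if (poisson) {
    for (int i = 0; i < n; ++i) {
      const double mi = std::max(m[i], 1e-12);
      obj += mi - counts[i] * std::log(mi);
    }
  } else {
    for (int i = 0; i < n; ++i) {
      const double r = counts[i] - m[i];
      obj += r * r / std::max(counts[i], 1.0);
    }
  }
  return obj;
}
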