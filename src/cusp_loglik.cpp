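#include <Rcpp.h>
using namespace Rcpp;

// Stationary density of the canonical cusp SDE:
//   f(z | a, b) = exp(a*z + b*z^2/2 - z^4/4) / N(a, b)
// N(a, b) is computed by trapezoid quadrature on a uniform node grid.
// The quartic tail makes the integrand effectively compactly supported,
// so the uniform-grid trapezoid rule converges spectrally (all
// Euler-Maclaurin boundary terms vanish).

// Per-observation log-normalizer and first two moments of the density.
// [[Rcpp::export]]
List cusp_quad_moments(NumericVector alpha, NumericVector beta,
                       NumericVector nodes, double h) {
  const int T = alpha.size();
  const int n = nodes.size();
  NumericVector logN(T), Ez(T), Ez2(T);
  std::vector<double> e(n);
  for (int t = 0; t < T; ++t) {
    const double a = alpha[t], b = beta[t];
    double m = R_NegInf;
    for (int i = 0; i < n; ++i) {
      const double u = nodes[i];
      const double u2 = u * u;
      e[i] = a * u + 0.5 * b * u2 - 0.25 * u2 * u2;
      if (e[i] > m) m = e[i];
    }
    double s0 = 0.0, s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double w = std::exp(e[i] - m);
      const double u = nodes[i];
      s0 += w;
      s1 += w * u;
      s2 += w * u * u;
    }
    logN[t] = m + std::log(s0 * h);
    Ez[t]  = s1 / s0;
    Ez2[t] = s2 / s0;
  }
  return List::create(_["logN"] = logN, _["Ez"] = Ez, _["Ez2"] = Ez2);
}

// Negative log-likelihood and analytic gradient of the cusp fit with
// linear submodels:
//   z_t     = w0 + w1 * y_t
//   alpha_t = a0 + a1 * xa_t
//   beta_t  = b0 + b1 * xb_t
//   loglik  = sum_t log f(z_t | alpha_t, beta_t) + T * log|w1|
// par = (a0, a1, b0, b1, w0, w1).
// [[Rcpp::export]]
List cusp_negloglik(NumericVector par, NumericVector y,
                    NumericVector xa, NumericVector xb,
                    NumericVector nodes, double h) {
  const int T = y.size();
  const int n = nodes.size();
  const double a0 = par[0], a1 = par[1], b0 = par[2], b1 = par[3];
  const double w0 = par[4], w1 = par[5];
  double nll = 0.0;
  NumericVector grad(6);
  if (w1 == 0.0 || !std::isfinite(w1)) {
    return List::create(_["value"] = 1e10, _["gradient"] = grad);
  }
  std::vector<double> e(n);
  for (int t = 0; t < T; ++t) {
    const double at = a0 + a1 * xa[t];
    const double bt = b0 + b1 * xb[t];
    const double zt = w0 + w1 * y[t];
    if (!std::isfinite(at) || !std::isfinite(bt) || !std::isfinite(zt)) {
      return List::create(_["value"] = 1e10, _["gradient"] = NumericVector(6));
    }
    double m = R_NegInf;
    for (int i = 0; i < n; ++i) {
      const double u = nodes[i];
      const double u2 = u * u;
      e[i] = at * u + 0.5 * bt * u2 - 0.25 * u2 * u2;
      if (e[i] > m) m = e[i];
    }
    double s0 = 0.0, s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double w = std::exp(e[i] - m);
      const double u = nodes[i];
      s0 += w;
      s1 += w * u;
      s2 += w * u * u;
    }
    const double logN = m + std::log(s0 * h);
    const double Ez = s1 / s0, Ez2 = s2 / s0;
    const double z2 = zt * zt;
    nll -= at * zt + 0.5 * bt * z2 - 0.25 * z2 * z2 - logN;
    // d(nll)/d(par): residuals of z and z^2 against their model moments
    const double rz = zt - Ez;
    const double rz2 = 0.5 * (z2 - Ez2);
    const double dldz = at + bt * zt - zt * z2;  // d loglik / d z_t
    grad[0] -= rz;
    grad[1] -= rz * xa[t];
    grad[2] -= rz2;
    grad[3] -= rz2 * xb[t];
    grad[4] -= dldz;
    grad[5] -= dldz * y[t];
  }
  nll -= T * std::log(std::fabs(w1));
  grad[5] -= T / w1;
  if (!std::isfinite(nll)) {
    return List::create(_["value"] = 1e10, _["gradient"] = NumericVector(6));
  }
  return List::create(_["value"] = nll, _["gradient"] = grad);
}
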