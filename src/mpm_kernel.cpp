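// Forward projection of the mean size distribution and reverse-mode
// (adjoint) gradient of the Dirichlet-multinomial log likelihood with
// respect to the per-step transition fractions, the initial distribution
// and the concentration parameter. The chain rule from fractions back to
// model parameters is applied in R, where it is a handful of small matrix
// products; this kernel carries the per-step recursion, which dominates
// the cost of a gradient evaluation.

#include <Rcpp.h>
using namespace Rcpp;

// Dirichlet-multinomial log pmf and its partials. omega must be strictly
// positive wherever n > 0; callers guarantee this (the projection keeps the
// distribution interior for interior initial conditions).
static double dm_loglik(const double* n, const double* omega, double sigma,
                        int m, double* domega, double* dsigma) {
  double N = 0.0;
  for (int i = 0; i < m; ++i) N += n[i];
  double ll = R::lgammafn(sigma) + R::lgammafn(N + 1.0) - R::lgammafn(N + sigma);
  double ds = R::digamma(sigma) - R::digamma(N + sigma);
  for (int i = 0; i < m; ++i) {
    double a = sigma * omega[i];
    if (n[i] > 0.0 && !(a > 0.0)) return R_NegInf;
    if (n[i] > 0.0) {
      ll += R::lgammafn(n[i] + a) - R::lgammafn(a) - R::lgammafn(n[i] + 1.0);
      double d = R::digamma(n[i] + a) - R::digamma(a);
      if (domega) domega[i] += sigma * d;
      ds += omega[i] * d;
    }
  }
  if (dsigma) *dsigma += ds;
  return ll;
}

// [[Rcpp::export]]
List mpm_loglik_grad_cpp(NumericMatrix delta,   // m x S per-step division fractions
                         NumericMatrix gamma,   // m x S per-step growth fractions
                         NumericVector rho,     // m     per-step loss fractions
                         NumericVector omega0,  // m     initial simplex
                         double sigma,
                         NumericMatrix counts,     // m x K counts per obs time
                         IntegerVector obs_steps,  // K, 0-based step index of each obs
                         int j,                    // 1-based smallest dividing class
                         bool include_k0,
                         bool need_grad) {
  const int m = delta.nrow();
  const int S = delta.ncol();
  const int K = obs_steps.size();
  const int jj = j - 1;  // 0-based

  // forward pass: store omega at every lattice point
  NumericMatrix om(m, S + 1);
  NumericVector g(S);
  for (int i = 0; i < m; ++i) om(i, 0) = omega0[i];
  std::vector<double> u(m);
  for (int s = 0; s < S; ++s) {
    const double* d = &delta(0, s);
    const double* ga = &gamma(0, s);
    const double* w = &om(0, s);
    std::fill(u.begin(), u.end(), 0.0);
    for (int i = 0; i < m; ++i) {
      double od = 1.0 - d[i], og = 1.0 - ga[i], orh = 1.0 - rho[i];
      u[i] += od * og * orh * w[i];               // stasis
      if (i + 1 < m) u[i + 1] += od * orh * ga[i] * w[i];  // growth
      if (i > 0) u[i - 1] += od * rho[i] * w[i];           // loss
      if (i >= jj) u[i - jj] += 2.0 * d[i] * w[i];         // division
    }
    double gs = 0.0;
    for (int i = 0; i < m; ++i) gs += u[i];
    if (!(gs > 0.0) || !R_finite(gs)) {
      return List::create(_["loglik"] = R_NegInf);
    }
    g[s] = gs;
    for (int i = 0; i < m; ++i) om(i, s + 1) = u[i] / gs;
  }

  // likelihood at observation times
  double ll = 0.0;
  double dsigma = 0.0;
  for (int k = 0; k < K; ++k) {
    int s = obs_steps[k];
    if (s == 0 && !include_k0) continue;
    ll += dm_loglik(&counts(0, k), &om(0, s), sigma, m, nullptr, nullptr);
  }
  if (!R_finite(ll) || !need_grad) {
    return List::create(_["loglik"] = ll, _["growth"] = g,
                        _["omegas"] = om);
  }

  // reverse pass
  NumericMatrix dDelta(m, S), dGamma(m, S);
  NumericVector dRho(m), dOmega0(m);
  std::vector<double> obar(m, 0.0), ubar(m), obar_prev(m);
  // map step index -> observation index (or -1)
  std::vector<int> obs_of(S + 1, -1);
  for (int k = 0; k < K; ++k) obs_of[obs_steps[k]] = k;

  for (int s = S; s >= 1; --s) {
    int k = obs_of[s];
    if (k >= 0) {
      dm_loglik(&counts(0, k), &om(0, s), sigma, m, obar.data(), &dsigma);
    }
    // u = W omega_{s-1}; omega_s = u / g; ubar = (obar - <obar, omega_s>) / g
    double dot = 0.0;
    for (int i = 0; i < m; ++i) dot += obar[i] * om(i, s);
    double gs = g[s - 1];
    for (int i = 0; i < m; ++i) ubar[i] = (obar[i] - dot) / gs;

    const double* d = &delta(0, s - 1);
    const double* ga = &gamma(0, s - 1);
    const double* w = &om(0, s - 1);
    for (int i = 0; i < m; ++i) {
      double od = 1.0 - d[i], og = 1.0 - ga[i], orh = 1.0 - rho[i];
      double ub_self = ubar[i];
      double ub_up = (i + 1 < m) ? ubar[i + 1] : 0.0;
      double ub_dn = (i > 0) ? ubar[i - 1] : 0.0;
      double ub_div = (i >= jj) ? ubar[i - jj] : 0.0;
      obar_prev[i] = od * og * orh * ub_self + od * orh * ga[i] * ub_up +
                     od * rho[i] * ub_dn + 2.0 * d[i] * ub_div;
      if (i + 1 < m) {
        dGamma(i, s - 1) = w[i] * od * orh * (ub_up - ub_self);
      }
      if (i > 0) {
        dRho[i] += w[i] * od * (ub_dn - ga[i] * ub_up - og * ub_self);
      }
      if (i >= jj) {
        dDelta(i, s - 1) = w[i] * (2.0 * ub_div - orh * ga[i] * ub_up -
                                   rho[i] * ub_dn - og * orh * ub_self);
      }
    }
    std::swap(obar, obar_prev);
    std::fill(obar_prev.begin(), obar_prev.end(), 0.0);
  }
  if (obs_of[0] >= 0 && include_k0) {
    dm_loglik(&counts(0, obs_of[0]), &om(0, 0), sigma, m, obar.data(), &dsigma);
  }
  for (int i = 0; i < m; ++i) dOmega0[i] = obar[i];

  return List::create(_["loglik"] = ll, _["growth"] = g, _["omegas"] = om,
                      _["d_delta"] = dDelta, _["d_gamma"] = dGamma,
                      _["d_rho"] = dRho, _["d_omega0"] = dOmega0,
                      _["d_sigma"] = dsigma);
}

// Agent-free forward projection of raw (unnormalized) counts for the
// Monte-Carlo oracle comparisons: expected class counts after S steps.
// [[Rcpp::export]]
NumericVector mpm_project_counts_cpp(NumericMatrix delta, NumericMatrix gamma,
                                     NumericVector rho, NumericVector x0, int j) {
  const int m = delta.nrow();
  const int S = delta.ncol();
  const int jj = j - 1;
  std::vector<double> x(x0.begin(), x0.end()), u(m);
  for (int s = 0; s < S; ++s) {
    const double* d = &delta(0, s);
    const double* ga = &gamma(0, s);
    std::fill(u.begin(), u.end(), 0.0);
    for (int i = 0; i < m; ++i) {
      double od = 1.0 - d[i], og = 1.0 - ga[i], orh = 1.0 - rho[i];
      u[i] += od * og * orh * x[i];
      if (i + 1 < m) u[i + 1] += od * orh * ga[i] * x[i];
      if (i > 0) u[i - 1] += od * rho[i] * x[i];
      if (i >= jj) u[i - jj] += 2.0 * d[i] * x[i];
    }
    x = u;
  }
  return NumericVector(x.begin(), x.end());
}
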