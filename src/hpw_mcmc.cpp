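#include <Rcpp.h>
using namespace Rcpp;

// Forward-filter backward-sample for the binary confinement chain.
// logf0/logf1: per-increment emission log-densities under free/confined.
// Filtering is done on per-step normalized probabilities (emissions
// shifted by their per-step max), which is underflow-safe.
// [[Rcpp::export]]
IntegerVector ffbs_binary_cpp(NumericVector logf0, NumericVector logf1,
                              double p_esc, double p_trap, double pi1) {
  const int m = logf0.size();
  if (logf1.size() != m) stop("emission vectors differ in length");
  NumericMatrix alpha(2, m);

  // transition matrix T(j,k) = P(z'=k | z=j)
  const double t00 = 1.0 - p_trap, t01 = p_trap;
  const double t10 = p_esc,        t11 = 1.0 - p_esc;

  double mx = std::max(logf0[0], logf1[0]);
  double a0 = (1.0 - pi1) * std::exp(logf0[0] - mx);
  double a1 = pi1 * std::exp(logf1[0] - mx);
  double s = a0 + a1;
  alpha(0, 0) = a0 / s;
  alpha(1, 0) = a1 / s;

  for (int t = 1; t < m; ++t) {
    mx = std::max(logf0[t], logf1[t]);
    double p0 = alpha(0, t - 1) * t00 + alpha(1, t - 1) * t10;
    double p1 = alpha(0, t - 1) * t01 + alpha(1, t - 1) * t11;
    a0 = p0 * std::exp(logf0[t] - mx);
    a1 = p1 * std::exp(logf1[t] - mx);
    s = a0 + a1;
    if (s <= 0.0) { a0 = p0; a1 = p1; s = a0 + a1; }
    alpha(0, t) = a0 / s;
    alpha(1, t) = a1 / s;
  }

  IntegerVector z(m);
  z[m - 1] = (unif_rand() < alpha(1, m - 1)) ? 1 : 0;
  for (int t = m - 2; t >= 0; --t) {
    double w0, w1;
    if (z[t + 1] == 1) { w0 = alpha(0, t) * t01; w1 = alpha(1, t) * t11; }
    else               { w0 = alpha(0, t) * t00; w1 = alpha(1, t) * t10; }
    z[t] = (unif_rand() * (w0 + w1) < w1) ? 1 : 0;
  }
  return z;
}

// Exact forward-filter backward-sample for a scalar AR(1)-with-offset
// state observed through Gaussian noise at a subset of steps.
//   state:  s[t+1] = phi[t] * s[t] + u[t] + N(0, q[t]),  t = 1..m-1
//   obs:    y[t] = s[t] + N(0, r[t])     where has_obs[t]
//   prior:  s[1] ~ N(m0, v0)
// The plain random walk is phi = 1, u = 0; phi < 1 with u = alpha*dt*x
// implements a drift toward a target (used during burn-in only).
// var_floor guards against singular filters when q is sampled very small.
// [[Rcpp::export]]
NumericVector kalman_ffbs_cpp(NumericVector y, NumericVector r,
                              LogicalVector has_obs, NumericVector q,
                              NumericVector phi, NumericVector u,
                              double m0, double v0, double var_floor) {
  const int m = y.size();
  if (r.size() != m || has_obs.size() != m || q.size() != m - 1 ||
      phi.size() != m - 1 || u.size() != m - 1)
    stop("inconsistent lengths in kalman_ffbs_cpp");
  NumericVector fm(m), fv(m);

  double pm = m0, pv = v0;
  for (int t = 0; t < m; ++t) {
    if (t > 0) {
      pm = phi[t - 1] * fm[t - 1] + u[t - 1];
      pv = phi[t - 1] * phi[t - 1] * fv[t - 1] + std::max(q[t - 1], var_floor);
    }
    if (has_obs[t]) {
      double rr = std::max(r[t], var_floor);
      double k = pv / (pv + rr);
      fm[t] = pm + k * (y[t] - pm);
      fv[t] = (1.0 - k) * pv;
    } else {
      fm[t] = pm;
      fv[t] = pv;
    }
    if (fv[t] < var_floor) fv[t] = var_floor;
  }

  NumericVector s(m);
  s[m - 1] = fm[m - 1] + std::sqrt(fv[m - 1]) * norm_rand();
  for (int t = m - 2; t >= 0; --t) {
    double qq = std::max(q[t], var_floor);
    double g = phi[t] * fv[t] / (phi[t] * phi[t] * fv[t] + qq);
    double mean = fm[t] + g * (s[t + 1] - phi[t] * fm[t] - u[t]);
    double var = fv[t] - g * phi[t] * fv[t];
    if (var < var_floor) var = var_floor;
    s[t] = mean + std::sqrt(var) * norm_rand();
  }
  return s;
}
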