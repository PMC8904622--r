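#include <Rcpp.h>
#include "wfpt.h"
using namespace Rcpp;

// Vectorized WFPT log density for observed (rt, boundary_hit) pairs.
// upper: 1 = upper-boundary absorption, 0 = lower. rt <= ndt yields -Inf
// by contract so samplers can reject rather than error.
// [[Rcpp::export(name = ".wfpt_log_density_cpp")]]
NumericVector wfpt_log_density_cpp(NumericVector rt, IntegerVector upper,
                                   double drift, double boundary, double ndt,
                                   double start_frac) {
  const int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double t = rt[i] - ndt;
    out[i] = wfpt::log_density(t, upper[i] != 0, drift, boundary, start_frac,
                               nullptr, nullptr, nullptr);
  }
  return out;
}

// Gradient of the WFPT log density wrt (drift, boundary, ndt); used by the
// finite-difference smoothness tests.
// [[Rcpp::export(name = ".wfpt_log_density_grad_cpp")]]
NumericMatrix wfpt_log_density_grad_cpp(NumericVector rt, IntegerVector upper,
                                        double drift, double boundary,
                                        double ndt, double start_frac) {
  const int n = rt.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double dv = NA_REAL, da = NA_REAL, dt = NA_REAL;
    const double t = rt[i] - ndt;
    wfpt::log_density(t, upper[i] != 0, drift, boundary, start_frac,
                      &dv, &da, &dt);
    out(i, 0) = dv;
    out(i, 1) = da;
    out(i, 2) = -dt;  // d/d ndt = -d/dt
  }
  return out;
}

// Euler-Maruyama simulation of the simple diffusion process with 1 ms
// default step, within-trial noise SD 1, absorbing boundaries at 0 and a.
// A Brownian-bridge correction accounts for within-step boundary crossings,
// removing the O(sqrt(dt)) first-exit bias of the naive scheme. Trials not
// absorbed by t_max are flagged censored (rt = NA).
// [[Rcpp::export(name = ".ddm_simulate_cpp")]]
List ddm_simulate_cpp(int n, double drift, double boundary, double ndt,
                      double start_frac, double dt, double t_max) {
  NumericVector rt(n);
  IntegerVector upper(n), censored(n);
  const double sqdt = std::sqrt(dt);
  const int max_steps = (int)std::ceil(t_max / dt);
  for (int i = 0; i < n; ++i) {
    double x = start_frac * boundary;
    int step = 0;
    bool hit = false;
    double hit_frac = 0.0;  // fraction of the final step already elapsed
    while (step < max_steps) {
      ++step;
      const double x0 = x;
      x += drift * dt + sqdt * norm_rand();
      if (x >= boundary) { upper[i] = 1; hit = true; break; }
      if (x <= 0.0)      { upper[i] = 0; hit = true; break; }
      // bridge probability of an unobserved within-step crossing
      const double pu = std::exp(-2.0 * (boundary - x0) * (boundary - x) / dt);
      const double pl = std::exp(-2.0 * x0 * x / dt);
      const double u = unif_rand();
      if (u < pu)            { upper[i] = 1; hit = true; hit_frac = 0.5; break; }
      else if (u < pu + pl)  { upper[i] = 0; hit = true; hit_frac = 0.5; break; }
    }
    if (hit) {
      rt[i] = (step - hit_frac) * dt + ndt;
      censored[i] = 0;
    } else {
      rt[i] = NA_REAL;
      upper[i] = NA_INTEGER;
      censored[i] = 1;
    }
  }
  return List::create(_["rt"] = rt, _["upper"] = upper,
                      _["censored"] = censored);
}
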