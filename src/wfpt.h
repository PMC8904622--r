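#ifndef DRIFTBAND_WFPT_H
#define DRIFTBAND_WFPT_H

#include <cmath>

// Wiener first-passage-time density for the simple diffusion model
// (within-trial noise SD fixed to 1). Series machinery follows the
// small-time / large-time decomposition of Navarro & Fuss (2009),
// J Math Psychol 53:222-230, extended with term-wise derivatives so the
// log-density gradient wrt (drift, boundary, ndt) is analytic.

namespace wfpt {

// f_tt(u, w): first-passage density at normalized time u = t / a^2 for a
// unit-boundary, zero-drift process started at relative position w.
// Returns the density and (optionally) its derivative wrt u.
// err is an absolute truncation tolerance on the density value.
inline void ftt(double u, double w, double err, double* f, double* dfdu) {
  const double pi = M_PI;
  // number of terms needed for each expansion (Navarro & Fuss eqs. 10-13)
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * pi * u) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * err * std::sqrt(2.0 * pi * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (pi * u * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(pi * u * err) / (pi * pi * u));
    kl = std::max(kl, 1.0 / (pi * std::sqrt(u)));
  } else {
    kl = 1.0 / (pi * std::sqrt(u));
  }

  double F = 0.0, dF = 0.0;
  if (ks < kl) {
    // small-time expansion: sum over mirrored start positions
    const int K = (int)std::ceil(ks);
    const int lo = -((K - 1) / 2), hi = ((K - 1) / 2) + ((K - 1) % 2);
    const double c0 = 1.0 / std::sqrt(2.0 * pi * u * u * u);
    for (int k = lo; k <= hi; ++k) {
      const double z = w + 2.0 * k;
      const double e = std::exp(-z * z / (2.0 * u));
      F += z * e;
      // d/du of z*exp(-z^2/2u) * u^{-3/2} handled after the loop for the
      // u^{-3/2} factor; here accumulate the exp-part derivative
      dF += z * e * (z * z / (2.0 * u * u));
    }
    if (dfdu) *dfdu = c0 * dF - 1.5 / u * c0 * F;
    F *= c0;
  } else {
    // large-time expansion: eigenfunction series
    const int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      const double lam = k * k * pi * pi / 2.0;
      const double e = std::exp(-lam * u);
      const double s = std::sin(k * pi * w);
      F += k * e * s;
      dF += -lam * k * e * s;
    }
    F *= pi;
    if (dfdu) *dfdu = pi * dF;
  }
  *f = F;
}

// Log density of hitting the LOWER boundary at decision time t (> 0) for
// drift v, boundary separation a, relative start w. Optionally fills the
// gradient wrt v, a and t. Returns -Inf when the density underflows.
inline double log_density_lower(double t, double v, double a, double w,
                                double* dv, double* da, double* dt) {
  if (!(t > 0.0) || !(a > 0.0)) return -INFINITY;
  const double u = t / (a * a);
  double f, dfdu;
  ftt(u, w, 1e-12, &f, &dfdu);
  if (!(f > 0.0) || !std::isfinite(f)) return -INFINITY;
  const double lp = -2.0 * std::log(a) + std::log(f) - v * a * w - 0.5 * v * v * t;
  const double r = dfdu / f;  // d log f_tt / du
  if (dv) *dv = -a * w - v * t;
  if (da) *da = -2.0 / a - v * w + r * (-2.0 * t / (a * a * a));
  if (dt) *dt = -0.5 * v * v + r / (a * a);
  return lp;
}

// Log density for an observed (choice, rt) pair. upper = true means the
// process was absorbed at the upper boundary: by reflection this equals the
// lower-boundary density with v -> -v, w -> 1 - w.
inline double log_density(double t, bool upper, double v, double a, double w,
                          double* dv, double* da, double* dt) {
  if (upper) {
    double lp = log_density_lower(t, -v, a, 1.0 - w, dv, da, dt);
    if (dv) *dv = -*dv;
    return lp;
  }
  return log_density_lower(t, v, a, w, dv, da, dt);
}

}  // namespace wfpt

#endif
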