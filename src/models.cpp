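#include <Rcpp.h>
#include "nuts.h"
#include "wfpt.h"
using namespace Rcpp;

// Hierarchical Bayesian models sampled with the in-package NUTS engine.
// All models live on an unconstrained scale; positivity-constrained scale
// parameters are sampled as logs with the Jacobian added to the target.
// Priors follow the broad, weakly informative scheme used for fitting:
//   * condition-level locations and regression coefficients: Normal(0, 20)
//     on the "primed" offset-from-first parameterization (first boundary
//     location Normal(1, 20), biased positive);
//   * non-decision time: group mean Normal(0.5, 1) seconds, group SD
//     half-Normal(0, 1); subject values Gaussian under those, mapped through
//     a scaled logit so ndt stays inside (0, min RT) per subject;
//   * subject drift/boundary deviations: Normal(0, sigma) with
//     half-Normal(0, 20) on sigma, non-centered.

static const double COEF_SD = 20.0;

static inline double sq(double x) { return x * x; }

// ---------------------------------------------------------------------------
// Drift-diffusion regression model (4 variants)
// ---------------------------------------------------------------------------

class DDMHierModel : public nuts::Model {
 public:
  // trials
  std::vector<int> subj, cond;        // 0-based
  std::vector<double> rt;
  std::vector<int> correct;           // 1 = upper boundary (accuracy coding)
  int S = 0, C = 6;
  std::vector<double> ndt_ub;         // per-subject upper bound for ndt
  // covariates (z-scored upstream)
  std::vector<double> padua, worry;   // length S
  std::vector<double> gam, bet;       // S*C, column-major by condition
  bool has_sym = false, has_neu = false;

  // parameter offsets
  int o_dvp, o_bvp, o_mu_ndt, o_ls_ndt, o_eta, o_lsd, o_zd, o_lsb, o_zb,
      o_sym, o_neu, npar_;

  void finalize() {
    o_dvp = 0; o_bvp = 6; o_mu_ndt = 12; o_ls_ndt = 13; o_eta = 14;
    o_lsd = o_eta + S; o_zd = o_lsd + 1; o_lsb = o_zd + S; o_zb = o_lsb + 1;
    int off = o_zb + S;
    o_sym = off; if (has_sym) off += 24;
    o_neu = off; if (has_neu) off += 24;
    npar_ = off;
  }

  int n_par() const override { return npar_; }

  // offset-from-first transform: out[0] = p[0]; out[c] = p[0] + p[c]
  static void unprime(const double* p, double* out) {
    out[0] = p[0];
    for (int c = 1; c < 6; ++c) out[c] = p[0] + p[c];
  }

  double lp_grad(const double* q, double* grad) const override {
    const int P = npar_;
    for (int i = 0; i < P; ++i) grad[i] = 0.0;
    double lp = 0.0;

    // --- unpack & priors on primed locations/coefficients ---
    auto prior_n0 = [&](int idx, double mean, double sd) {
      lp += -0.5 * sq((q[idx] - mean) / sd);
      grad[idx] += -(q[idx] - mean) / (sd * sd);
    };
    for (int c = 0; c < 6; ++c) prior_n0(o_dvp + c, 0.0, COEF_SD);
    prior_n0(o_bvp, 1.0, COEF_SD);
    for (int c = 1; c < 6; ++c) prior_n0(o_bvp + c, 0.0, COEF_SD);
    if (has_sym) for (int k = 0; k < 24; ++k) prior_n0(o_sym + k, 0.0, COEF_SD);
    if (has_neu) for (int k = 0; k < 24; ++k) prior_n0(o_neu + k, 0.0, COEF_SD);

    const double mu_ndt = q[o_mu_ndt];
    prior_n0(o_mu_ndt, 0.5, 1.0);
    const double sig_ndt = std::exp(q[o_ls_ndt]);
    // half-Normal(0,1) on sigma_ndt plus log Jacobian
    lp += -0.5 * sq(sig_ndt) + q[o_ls_ndt];
    grad[o_ls_ndt] += -sq(sig_ndt) + 1.0;

    const double sig_d = std::exp(q[o_lsd]);
    lp += -0.5 * sq(sig_d / COEF_SD) + q[o_lsd];
    grad[o_lsd] += -sq(sig_d) / sq(COEF_SD) + 1.0;
    const double sig_b = std::exp(q[o_lsb]);
    lp += -0.5 * sq(sig_b / COEF_SD) + q[o_lsb];
    grad[o_lsb] += -sq(sig_b) / sq(COEF_SD) + 1.0;

    // subject deviations (non-centered) and ndt
    std::vector<double> ndt(S), drift_s(S), bound_s(S);
    for (int s = 0; s < S; ++s) {
      const double z1 = q[o_zd + s], z2 = q[o_zb + s];
      lp += -0.5 * sq(z1) - 0.5 * sq(z2);
      grad[o_zd + s] += -z1;
      grad[o_zb + s] += -z2;
      drift_s[s] = sig_d * z1;
      bound_s[s] = sig_b * z2;

      const double L = ndt_ub[s];
      const double il = 1.0 / (1.0 + std::exp(-q[o_eta + s]));
      const double nd = L * il;
      ndt[s] = nd;
      // Gaussian prior on ndt + logit-scale Jacobian log(nd (L-nd) / L)
      lp += -std::log(sig_ndt) - 0.5 * sq((nd - mu_ndt) / sig_ndt)
            + std::log(nd * (L - nd) / L);
      const double dndt_deta = nd * (L - nd) / L;
      grad[o_eta + s] += -(nd - mu_ndt) / sq(sig_ndt) * dndt_deta
                         + (L - 2.0 * nd) / L;
      grad[o_mu_ndt] += (nd - mu_ndt) / sq(sig_ndt);
      grad[o_ls_ndt] += -1.0 + sq((nd - mu_ndt) / sig_ndt);
    }

    // condition locations (unprimed) and coefficient blocks
    double drift_c[6], bound_c[6];
    unprime(q + o_dvp, drift_c);
    unprime(q + o_bvp, bound_c);
    double dpad[6], dwor[6], bpad[6], bwor[6];
    double dgam[6], dbet[6], bgam[6], bbet[6];
    if (has_sym) {
      unprime(q + o_sym, dpad);      unprime(q + o_sym + 6, dwor);
      unprime(q + o_sym + 12, bpad); unprime(q + o_sym + 18, bwor);
    }
    if (has_neu) {
      unprime(q + o_neu, dgam);      unprime(q + o_neu + 6, dbet);
      unprime(q + o_neu + 12, bgam); unprime(q + o_neu + 18, bbet);
    }

    // cell-level drift/boundary and accumulators
    std::vector<double> v(S * C), a(S * C), gv(S * C, 0.0), ga(S * C, 0.0),
        gnd(S, 0.0);
    for (int s = 0; s < S; ++s) {
      for (int c = 0; c < C; ++c) {
        double vv = drift_c[c] + drift_s[s];
        double aa = bound_c[c] + bound_s[s];
        if (has_sym) {
          vv += dpad[c] * padua[s] + dwor[c] * worry[s];
          aa += bpad[c] * padua[s] + bwor[c] * worry[s];
        }
        if (has_neu) {
          const double g = gam[c * S + s], b = bet[c * S + s];
          vv += dgam[c] * g + dbet[c] * b;
          aa += bgam[c] * g + bbet[c] * b;
        }
        if (!(aa > 1e-3)) return -INFINITY;
        v[c * S + s] = vv;
        a[c * S + s] = aa;
      }
    }

    // WFPT likelihood
    const int N = (int)rt.size();
    for (int i = 0; i < N; ++i) {
      const int s = subj[i], c = cond[i], cell = c * S + s;
      const double t = rt[i] - ndt[s];
      double dv, da, dt;
      const double l = wfpt::log_density(t, correct[i] != 0, v[cell], a[cell],
                                         0.5, &dv, &da, &dt);
      if (!std::isfinite(l)) return -INFINITY;
      lp += l;
      gv[cell] += dv;
      ga[cell] += da;
      gnd[s] -= dt;  // d/d ndt = -d/dt
    }

    // --- backprop cell gradients ---
    for (int s = 0; s < S; ++s) {
      double sum_gv = 0.0, sum_ga = 0.0;
      for (int c = 0; c < C; ++c) {
        const double Gv = gv[c * S + s], Ga = ga[c * S + s];
        sum_gv += Gv; sum_ga += Ga;
        if (c > 0) {
          grad[o_dvp + c] += Gv;
          grad[o_bvp + c] += Ga;
        }
        if (has_sym) {
          const double ps = padua[s], ws = worry[s];
          if (c > 0) {
            grad[o_sym + c] += Gv * ps;       grad[o_sym + 6 + c] += Gv * ws;
            grad[o_sym + 12 + c] += Ga * ps;  grad[o_sym + 18 + c] += Ga * ws;
          }
          grad[o_sym] += Gv * ps;       grad[o_sym + 6] += Gv * ws;
          grad[o_sym + 12] += Ga * ps;  grad[o_sym + 18] += Ga * ws;
        }
        if (has_neu) {
          const double g = gam[c * S + s], b = bet[c * S + s];
          if (c > 0) {
            grad[o_neu + c] += Gv * g;       grad[o_neu + 6 + c] += Gv * b;
            grad[o_neu + 12 + c] += Ga * g;  grad[o_neu + 18 + c] += Ga * b;
          }
          grad[o_neu] += Gv * g;       grad[o_neu + 6] += Gv * b;
          grad[o_neu + 12] += Ga * g;  grad[o_neu + 18] += Ga * b;
        }
      }
      grad[o_dvp] += sum_gv;
      grad[o_bvp] += sum_ga;
      grad[o_zd + s] += sig_d * sum_gv;
      grad[o_zb + s] += sig_b * sum_ga;
      grad[o_lsd] += drift_s[s] * sum_gv;
      grad[o_lsb] += bound_s[s] * sum_ga;
      const double L = ndt_ub[s];
      grad[o_eta + s] += gnd[s] * ndt[s] * (L - ndt[s]) / L;
    }
    return lp;
  }

  // constrained, reporting-scale parameters
  int n_cpar() const {
    return 16 + 3 * S + (has_sym ? 24 : 0) + (has_neu ? 24 : 0);
  }
  void constrain(const double* q, double* out) const {
    int k = 0;
    double tmp[6];
    unprime(q + o_dvp, tmp); for (int c = 0; c < 6; ++c) out[k++] = tmp[c];
    unprime(q + o_bvp, tmp); for (int c = 0; c < 6; ++c) out[k++] = tmp[c];
    out[k++] = q[o_mu_ndt];
    out[k++] = std::exp(q[o_ls_ndt]);
    out[k++] = std::exp(q[o_lsd]);
    out[k++] = std::exp(q[o_lsb]);
    const double sig_d = std::exp(q[o_lsd]), sig_b = std::exp(q[o_lsb]);
    for (int s = 0; s < S; ++s)
      out[k++] = ndt_ub[s] / (1.0 + std::exp(-q[o_eta + s]));
    for (int s = 0; s < S; ++s) out[k++] = sig_d * q[o_zd + s];
    for (int s = 0; s < S; ++s) out[k++] = sig_b * q[o_zb + s];
    if (has_sym)
      for (int j = 0; j < 4; ++j) {
        unprime(q + o_sym + 6 * j, tmp);
        for (int c = 0; c < 6; ++c) out[k++] = tmp[c];
      }
    if (has_neu)
      for (int j = 0; j < 4; ++j) {
        unprime(q + o_neu + 6 * j, tmp);
        for (int c = 0; c < 6; ++c) out[k++] = tmp[c];
      }
  }
};

// [[Rcpp::export(name = ".fit_ddm_cpp")]]
List fit_ddm_cpp(IntegerVector subj, IntegerVector cond, NumericVector rt,
                 IntegerVector correct, int n_subjects,
                 NumericVector padua, NumericVector worry,
                 NumericMatrix gam, NumericMatrix bet,
                 bool has_sym, bool has_neu,
                 int chains, int warmup, int iter, int max_treedepth,
                 double ndt_ub_frac) {
  DDMHierModel m;
  m.subj = as<std::vector<int>>(subj);
  m.cond = as<std::vector<int>>(cond);
  m.rt = as<std::vector<double>>(rt);
  m.correct = as<std::vector<int>>(correct);
  m.S = n_subjects;
  m.has_sym = has_sym;
  m.has_neu = has_neu;
  m.padua = as<std::vector<double>>(padua);
  m.worry = as<std::vector<double>>(worry);
  m.gam.assign(n_subjects * 6, 0.0);
  m.bet.assign(n_subjects * 6, 0.0);
  if (has_neu) {
    for (int s = 0; s < n_subjects; ++s)
      for (int c = 0; c < 6; ++c) {
        m.gam[c * n_subjects + s] = gam(s, c);
        m.bet[c * n_subjects + s] = bet(s, c);
      }
  }
  // per-subject ndt upper bound: a fraction of that subject's fastest RT
  m.ndt_ub.assign(n_subjects, INFINITY);
  for (size_t i = 0; i < m.rt.size(); ++i)
    m.ndt_ub[m.subj[i]] = std::min(m.ndt_ub[m.subj[i]], m.rt[i]);
  for (int s = 0; s < n_subjects; ++s) {
    if (!std::isfinite(m.ndt_ub[s]))
      stop("subject %d has no trials", s + 1);
    m.ndt_ub[s] *= ndt_ub_frac;
  }
  m.finalize();

  nuts::Options opt;
  opt.warmup = warmup; opt.iter = iter; opt.max_treedepth = max_treedepth;

  const int P = m.n_par(), PC = m.n_cpar();
  List out(chains);
  IntegerVector div(chains), hits(chains);
  NumericVector steps(chains);
  for (int ch = 0; ch < chains; ++ch) {
    // dispersed initialization
    nuts::vec q0(P, 0.0);
    auto jit = [&](double sc) { return sc * (unif_rand() * 2.0 - 1.0); };
    q0[m.o_dvp] = 1.0 + jit(0.5);
    for (int c = 1; c < 6; ++c) q0[m.o_dvp + c] = jit(0.3);
    q0[m.o_bvp] = 1.5 + jit(0.3);
    for (int c = 1; c < 6; ++c) q0[m.o_bvp + c] = jit(0.2);
    q0[m.o_mu_ndt] = 0.3 + jit(0.05);
    q0[m.o_ls_ndt] = std::log(0.08) + jit(0.3);
    for (int s = 0; s < m.S; ++s) q0[m.o_eta + s] = 0.5 + jit(0.5);
    q0[m.o_lsd] = std::log(0.2) + jit(0.3);
    q0[m.o_lsb] = std::log(0.15) + jit(0.3);
    for (int s = 0; s < m.S; ++s) q0[m.o_zd + s] = jit(0.3);
    for (int s = 0; s < m.S; ++s) q0[m.o_zb + s] = jit(0.3);
    if (has_sym) for (int k = 0; k < 24; ++k) q0[m.o_sym + k] = jit(0.1);
    if (has_neu) for (int k = 0; k < 24; ++k) q0[m.o_neu + k] = jit(0.1);

    nuts::Sampler smp(m, opt);
    nuts::Result r = smp.run(q0);
    NumericMatrix draws(iter, PC);
    std::vector<double> cp(PC);
    for (int i = 0; i < iter; ++i) {
      m.constrain(r.draws[i].data(), cp.data());
      for (int j = 0; j < PC; ++j) draws(i, j) = cp[j];
    }
    out[ch] = draws;
    div[ch] = r.divergences;
    hits[ch] = r.treedepth_hits;
    steps[ch] = r.stepsize;
  }
  return List::create(_["chains"] = out, _["divergences"] = div,
                      _["treedepth_hits"] = hits, _["stepsize"] = steps,
                      _["n_subjects"] = n_subjects);
}

// ---------------------------------------------------------------------------
// Per-condition Gaussian regression of neural slopes on symptom scores,
// with hierarchically pooled intercepts across conditions
// ---------------------------------------------------------------------------

class GaussHierModel : public nuts::Model {
 public:
  int S = 0, C = 6;
  std::vector<double> y;             // S*C column-major
  std::vector<int> ok;               // 1 if observed
  std::vector<double> padua, worry;  // length S
  // layout: bmu0, ls_bsig0, b0[C], bpad[C], bwor[C], ls_sig[C]
  int n_par() const override { return 2 + 4 * C; }

  double lp_grad(const double* q, double* grad) const override {
    const int P = n_par();
    for (int i = 0; i < P; ++i) grad[i] = 0.0;
    double lp = 0.0;
    const double bmu0 = q[0];
    const double bsig0 = std::exp(q[1]);
    lp += -0.5 * sq(bmu0 / COEF_SD);
    grad[0] += -bmu0 / sq(COEF_SD);
    lp += -0.5 * sq(bsig0 / COEF_SD) + q[1];
    grad[1] += -sq(bsig0) / sq(COEF_SD) + 1.0;

    const double* b0 = q + 2;
    const double* bp = q + 2 + C;
    const double* bw = q + 2 + 2 * C;
    for (int c = 0; c < C; ++c) {
      // hierarchical intercept
      lp += -std::log(bsig0) - 0.5 * sq((b0[c] - bmu0) / bsig0);
      grad[2 + c] += -(b0[c] - bmu0) / sq(bsig0);
      grad[0] += (b0[c] - bmu0) / sq(bsig0);
      grad[1] += -1.0 + sq((b0[c] - bmu0) / bsig0);
      // coefficient priors
      lp += -0.5 * sq(bp[c] / COEF_SD) - 0.5 * sq(bw[c] / COEF_SD);
      grad[2 + C + c] += -bp[c] / sq(COEF_SD);
      grad[2 + 2 * C + c] += -bw[c] / sq(COEF_SD);
      // noise SD
      const double sig = std::exp(q[2 + 3 * C + c]);
      lp += -0.5 * sq(sig / COEF_SD) + q[2 + 3 * C + c];
      grad[2 + 3 * C + c] += -sq(sig) / sq(COEF_SD) + 1.0;
      for (int s = 0; s < S; ++s) {
        if (!ok[c * S + s]) continue;
        const double mu = b0[c] + bp[c] * padua[s] + bw[c] * worry[s];
        const double r = y[c * S + s] - mu;
        lp += -std::log(sig) - 0.5 * sq(r / sig);
        const double gmu = r / sq(sig);
        grad[2 + c] += gmu;
        grad[2 + C + c] += gmu * padua[s];
        grad[2 + 2 * C + c] += gmu * worry[s];
        grad[2 + 3 * C + c] += -1.0 + sq(r / sig);
      }
    }
    return lp;
  }

  int n_cpar() const { return 2 + 4 * C; }
  void constrain(const double* q, double* out) const {
    out[0] = q[0];
    out[1] = std::exp(q[1]);
    for (int c = 0; c < 3 * C; ++c) out[2 + c] = q[2 + c];
    for (int c = 0; c < C; ++c) out[2 + 3 * C + c] = std::exp(q[2 + 3 * C + c]);
  }
};

// [[Rcpp::export(name = ".fit_gauss_cpp")]]
List fit_gauss_cpp(NumericMatrix y, LogicalMatrix observed,
                   NumericVector padua, NumericVector worry,
                   int chains, int warmup, int iter, int max_treedepth) {
  GaussHierModel m;
  m.S = y.nrow(); m.C = y.ncol();
  m.y.assign(m.S * m.C, 0.0);
  m.ok.assign(m.S * m.C, 0);
  for (int s = 0; s < m.S; ++s)
    for (int c = 0; c < m.C; ++c) {
      m.y[c * m.S + s] = y(s, c);
      m.ok[c * m.S + s] = observed(s, c) ? 1 : 0;
    }
  m.padua = as<std::vector<double>>(padua);
  m.worry = as<std::vector<double>>(worry);

  nuts::Options opt;
  opt.warmup = warmup; opt.iter = iter; opt.max_treedepth = max_treedepth;
  const int P = m.n_par(), PC = m.n_cpar();
  List out(chains);
  IntegerVector div(chains), hits(chains);
  NumericVector steps(chains);
  for (int ch = 0; ch < chains; ++ch) {
    nuts::vec q0(P, 0.0);
    for (int i = 0; i < P; ++i) q0[i] = 0.1 * (unif_rand() * 2.0 - 1.0);
    q0[1] = std::log(0.5) + 0.2 * (unif_rand() * 2.0 - 1.0);
    for (int c = 0; c < m.C; ++c)
      q0[2 + 3 * m.C + c] = std::log(1.0) + 0.2 * (unif_rand() * 2.0 - 1.0);
    nuts::Sampler smp(m, opt);
    nuts::Result r = smp.run(q0);
    NumericMatrix draws(iter, PC);
    std::vector<double> cp(PC);
    for (int i = 0; i < iter; ++i) {
      m.constrain(r.draws[i].data(), cp.data());
      for (int j = 0; j < PC; ++j) draws(i, j) = cp[j];
    }
    out[ch] = draws;
    div[ch] = r.divergences; hits[ch] = r.treedepth_hits;
    steps[ch] = r.stepsize;
  }
  return List::create(_["chains"] = out, _["divergences"] = div,
                      _["treedepth_hits"] = hits, _["stepsize"] = steps);
}

// ---------------------------------------------------------------------------
// Multi-level logistic regression of trial difficulty on channel power
// ---------------------------------------------------------------------------

class LogisticHierModel : public nuts::Model {
 public:
  int N = 0, S = 0, C = 0;
  std::vector<double> X;   // N*C column-major by channel
  std::vector<int> y, subj;
  // layout: alpha0, ls_sig_alpha, z_alpha[S], mu_w[C], ls_tau, z_w[S*C]
  // tau is a single pooling SD shared across channels: with few subjects
  // per-channel SDs are unidentified and create 64 funnels
  int o_za, o_mu, o_lt, o_zw;
  void finalize() { o_za = 2; o_mu = 2 + S; o_lt = o_mu + C; o_zw = o_lt + 1; }
  int n_par() const override { return 2 + S + C + 1 + S * C; }

  double lp_grad(const double* q, double* grad) const override {
    const int P = n_par();
    for (int i = 0; i < P; ++i) grad[i] = 0.0;
    double lp = 0.0;
    const double a0 = q[0];
    const double siga = std::exp(q[1]);
    lp += -0.5 * sq(a0 / 2.5);
    grad[0] += -a0 / sq(2.5);
    lp += -0.5 * sq(siga) + q[1];
    grad[1] += -sq(siga) + 1.0;

    std::vector<double> alpha(S), w(S * C);
    for (int s = 0; s < S; ++s) {
      const double z = q[o_za + s];
      lp += -0.5 * sq(z);
      grad[o_za + s] += -z;
      alpha[s] = a0 + siga * z;
    }
    const double tau = std::exp(q[o_lt]);
    lp += -0.5 * sq(tau) + q[o_lt];
    grad[o_lt] += -sq(tau) + 1.0;
    for (int c = 0; c < C; ++c) {
      const double mu = q[o_mu + c];
      lp += -0.5 * sq(mu / 2.5);
      grad[o_mu + c] += -mu / sq(2.5);
      for (int s = 0; s < S; ++s) {
        const double z = q[o_zw + c * S + s];
        lp += -0.5 * sq(z);
        grad[o_zw + c * S + s] += -z;
        w[c * S + s] = mu + tau * z;
      }
    }

    std::vector<double> g_alpha(S, 0.0), g_w(S * C, 0.0);
    for (int i = 0; i < N; ++i) {
      const int s = subj[i];
      double eta = alpha[s];
      for (int c = 0; c < C; ++c) eta += w[c * S + s] * X[c * N + i];
      // Bernoulli-logit log density and gradient
      const double m = std::max(eta, 0.0);
      lp += y[i] * eta - (m + std::log(std::exp(-m) + std::exp(eta - m)));
      const double p = 1.0 / (1.0 + std::exp(-eta));
      const double r = y[i] - p;
      g_alpha[s] += r;
      for (int c = 0; c < C; ++c) g_w[c * S + s] += r * X[c * N + i];
    }
    for (int s = 0; s < S; ++s) {
      grad[0] += g_alpha[s];
      grad[1] += g_alpha[s] * (alpha[s] - a0);
      grad[o_za + s] += siga * g_alpha[s];
      for (int c = 0; c < C; ++c) {
        const double G = g_w[c * S + s];
        grad[o_mu + c] += G;
        grad[o_lt] += G * tau * q[o_zw + c * S + s];
        grad[o_zw + c * S + s] += tau * G;
      }
    }
    return lp;
  }

  // report group-level structure + subject intercepts
  int n_cpar() const { return 3 + S + C; }
  void constrain(const double* q, double* out) const {
    int k = 0;
    out[k++] = q[0];
    out[k++] = std::exp(q[1]);
    out[k++] = std::exp(q[o_lt]);
    for (int c = 0; c < C; ++c) out[k++] = q[o_mu + c];
    const double siga = std::exp(q[1]);
    for (int s = 0; s < S; ++s) out[k++] = q[0] + siga * q[o_za + s];
  }
};

// [[Rcpp::export(name = ".fit_logistic_cpp")]]
List fit_logistic_cpp(NumericMatrix X, IntegerVector y, IntegerVector subj,
                      int n_subjects, int chains, int warmup, int iter,
                      int max_treedepth) {
  LogisticHierModel m;
  m.N = X.nrow(); m.C = X.ncol(); m.S = n_subjects;
  m.X.assign(m.N * m.C, 0.0);
  for (int c = 0; c < m.C; ++c)
    for (int i = 0; i < m.N; ++i) m.X[c * m.N + i] = X(i, c);
  m.y = as<std::vector<int>>(y);
  m.subj = as<std::vector<int>>(subj);
  m.finalize();

  nuts::Options opt;
  opt.warmup = warmup; opt.iter = iter; opt.max_treedepth = max_treedepth;
  const int P = m.n_par(), PC = m.n_cpar();
  List out(chains);
  IntegerVector div(chains), hits(chains);
  NumericVector steps(chains);
  for (int ch = 0; ch < chains; ++ch) {
    nuts::vec q0(P, 0.0);
    for (int i = 0; i < P; ++i) q0[i] = 0.1 * (unif_rand() * 2.0 - 1.0);
    q0[1] = std::log(0.3) + 0.2 * (unif_rand() * 2.0 - 1.0);
    q0[m.o_lt] = std::log(0.3) + 0.2 * (unif_rand() * 2.0 - 1.0);
    nuts::Sampler smp(m, opt);
    nuts::Result r = smp.run(q0);
    NumericMatrix draws(iter, PC);
    std::vector<double> cp(PC);
    for (int i = 0; i < iter; ++i) {
      m.constrain(r.draws[i].data(), cp.data());
      for (int j = 0; j < PC; ++j) draws(i, j) = cp[j];
    }
    out[ch] = draws;
    div[ch] = r.divergences; hits[ch] = r.treedepth_hits;
    steps[ch] = r.stepsize;
  }
  return List::create(_["chains"] = out, _["divergences"] = div,
                      _["treedepth_hits"] = hits, _["stepsize"] = steps);
}

// ---------------------------------------------------------------------------
// Sampler self-check: correlated Gaussian target with known moments
// ---------------------------------------------------------------------------

class GaussTarget : public nuts::Model {
 public:
  int d = 2;
  double rho = 0.7;
  int n_par() const override { return d; }
  double lp_grad(const double* q, double* grad) const override {
    // pairwise AR(1)-style precision for an equicorrelated 2-d example,
    // generalized: independent blocks of bivariate normals
    double lp = 0.0;
    const double det = 1.0 - rho * rho;
    for (int i = 0; i + 1 < d; i += 2) {
      const double x = q[i], y = q[i + 1];
      lp += -(x * x - 2.0 * rho * x * y + y * y) / (2.0 * det);
      grad[i] = -(x - rho * y) / det;
      grad[i + 1] = -(y - rho * x) / det;
    }
    if (d % 2) {
      const double x = q[d - 1];
      lp += -0.5 * x * x;
      grad[d - 1] = -x;
    }
    return lp;
  }
};

// [[Rcpp::export(name = ".nuts_gauss_check_cpp")]]
NumericMatrix nuts_gauss_check_cpp(int d, double rho, int warmup, int iter) {
  GaussTarget m;
  m.d = d; m.rho = rho;
  nuts::Options opt;
  opt.warmup = warmup; opt.iter = iter;
  nuts::vec q0(d);
  for (int i = 0; i < d; ++i) q0[i] = unif_rand() * 2.0 - 1.0;
  nuts::Sampler smp(m, opt);
  nuts::Result r = smp.run(q0);
  NumericMatrix draws(iter, d);
  for (int i = 0; i < iter; ++i)
    for (int j = 0; j < d; ++j) draws(i, j) = r.draws[i][j];
  return draws;
}
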