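#ifndef DRIFTBAND_NUTS_H
#define DRIFTBAND_NUTS_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

// No-U-Turn sampler (Hoffman & Gelman 2014, Algorithm 6: slice variant with
// dual-averaging step-size adaptation), with a diagonal metric adapted over
// Stan-style expanding warmup windows. Works on the unconstrained scale; a
// model supplies the joint log density (priors + likelihood + Jacobians)
// and its gradient.

namespace nuts {

struct Model {
  virtual int n_par() const = 0;
  // returns log density; fills grad (length n_par); -Inf signals an
  // untenable state (the trajectory is rejected, never an error)
  virtual double lp_grad(const double* q, double* grad) const = 0;
  virtual ~Model() {}
};

typedef std::vector<double> vec;

struct Options {
  int warmup = 1000;
  int iter = 1000;        // retained draws
  int max_treedepth = 10;
  double delta = 0.8;     // dual-averaging target acceptance
};

struct Result {
  // draws on the unconstrained scale, iter x n_par
  std::vector<vec> draws;
  int divergences = 0;
  double stepsize = 0.0;
  int treedepth_hits = 0;  // iterations that saturated max_treedepth
};

class Sampler {
 public:
  Sampler(const Model& m, const Options& o) : model_(m), opt_(o), n_(m.n_par()),
      minv_(n_, 1.0) {}

  Result run(const vec& q0) {
    q_ = q0;
    g_.assign(n_, 0.0);
    lp_ = model_.lp_grad(q_.data(), g_.data());
    if (!std::isfinite(lp_)) Rcpp::stop("non-finite log density at the initial point");

    Result res;
    res.draws.reserve(opt_.iter);
    eps_ = find_reasonable_eps();
    da_reset(eps_);

    // metric adaptation windows inside [init_buf, warmup - term_buf)
    const int W = opt_.warmup;
    int init_buf = std::max(1, (int)(0.15 * W));
    int term_buf = std::max(1, (int)(0.10 * W));
    int win_start = init_buf, win_len = std::max(25, (W - init_buf - term_buf) / 8);

    welford_reset();
    for (int it = 0; it < W + opt_.iter; ++it) {
      const bool warm = it < W;
      double astat = transition();
      if (warm) {
        da_update(astat);
        eps_ = std::exp(log_eps_);
        if (it >= init_buf && it < W - term_buf) {
          welford_add(q_);
          const bool last_win = (win_start + win_len) >= (W - term_buf);
          if (it + 1 == win_start + win_len ||
              (last_win && it + 1 == W - term_buf)) {
            update_metric();
            welford_reset();
            win_start = it + 1;
            win_len *= 2;
            eps_ = find_reasonable_eps();
            da_reset(eps_);
          }
        }
        if (it == W - 1) eps_ = std::exp(log_eps_bar_);
      } else {
        res.draws.push_back(q_);
      }
      if (diverged_) res.divergences += (it >= W);
      if (depth_hit_) res.treedepth_hits += (it >= W);
      Rcpp::checkUserInterrupt();
    }
    res.stepsize = eps_;
    return res;
  }

 private:
  const Model& model_;
  Options opt_;
  int n_;
  vec minv_;          // inverse mass (per-coordinate scale^2)
  vec q_, g_;
  double lp_ = 0.0, eps_ = 1.0;
  bool diverged_ = false, depth_hit_ = false;

  // dual averaging state
  double mu_, log_eps_, log_eps_bar_, h_bar_;
  int da_t_;

  // Welford accumulator for the metric
  vec w_mean_, w_m2_;
  long w_n_ = 0;

  void da_reset(double eps0) {
    mu_ = std::log(10.0 * eps0);
    log_eps_ = std::log(eps0);
    log_eps_bar_ = 0.0;
    h_bar_ = 0.0;
    da_t_ = 0;
  }
  void da_update(double astat) {
    ++da_t_;
    const double t0 = 10.0, gamma = 0.05, kappa = 0.75;
    const double w = 1.0 / (da_t_ + t0);
    h_bar_ = (1.0 - w) * h_bar_ + w * (opt_.delta - astat);
    log_eps_ = mu_ - std::sqrt((double)da_t_) / gamma * h_bar_;
    const double w2 = std::pow((double)da_t_, -kappa);
    log_eps_bar_ = w2 * log_eps_ + (1.0 - w2) * log_eps_bar_;
  }

  void welford_reset() { w_mean_.assign(n_, 0.0); w_m2_.assign(n_, 0.0); w_n_ = 0; }
  void welford_add(const vec& q) {
    ++w_n_;
    for (int i = 0; i < n_; ++i) {
      const double d = q[i] - w_mean_[i];
      w_mean_[i] += d / w_n_;
      w_m2_[i] += d * (q[i] - w_mean_[i]);
    }
  }
  void update_metric() {
    if (w_n_ < 10) return;
    const double shrink = (double)w_n_ / (w_n_ + 5.0);
    for (int i = 0; i < n_; ++i) {
      double v = w_m2_[i] / (w_n_ - 1);
      minv_[i] = shrink * v + (1.0 - shrink) * 1e-3;
      if (!(minv_[i] > 1e-10)) minv_[i] = 1e-10;
    }
  }

  double hamiltonian(double lp, const vec& p) const {
    double ke = 0.0;
    for (int i = 0; i < n_; ++i) ke += minv_[i] * p[i] * p[i];
    return lp - 0.5 * ke;
  }

  // one leapfrog step in place; returns the new log density
  double leapfrog(vec& q, vec& p, vec& g, double dir) const {
    const double e = dir * eps_;
    for (int i = 0; i < n_; ++i) p[i] += 0.5 * e * g[i];
    for (int i = 0; i < n_; ++i) q[i] += e * minv_[i] * p[i];
    double lp = model_.lp_grad(q.data(), g.data());
    if (std::isfinite(lp)) {
      for (int i = 0; i < n_; ++i) p[i] += 0.5 * e * g[i];
    }
    return lp;
  }

  // one-leapfrog Hamiltonian change at a trial step size
  double probe(double eps) {
    vec p(n_), q(q_), g(g_);
    for (int i = 0; i < n_; ++i) p[i] = norm_rand() / std::sqrt(minv_[i]);
    const double H0 = hamiltonian(lp_, p);
    const double save_eps = eps_;
    eps_ = eps;
    const double lp1 = leapfrog(q, p, g, 1.0);
    eps_ = save_eps;
    return (std::isfinite(lp1) ? hamiltonian(lp1, p) : -INFINITY) - H0;
  }

  double find_reasonable_eps() {
    double eps = 0.1;
    double ratio = probe(eps);
    const double dir = (ratio > std::log(0.5)) ? 1.0 : -1.0;
    for (int tries = 0; tries < 60; ++tries) {
      eps *= (dir > 0) ? 2.0 : 0.5;
      ratio = probe(eps);
      if (dir > 0 && !(ratio > std::log(0.5))) { eps *= 0.5; break; }
      if (dir < 0 && !(ratio < std::log(0.5))) break;
    }
    return std::max(std::min(eps, 10.0), 1e-8);
  }

  struct Tree {
    vec qm, pm, gm, qp, pp, gp;  // backward / forward ends
    vec qprop;                   // proposal within the subtree
    int n = 0;                   // slice-valid states
    bool ok = true;              // no U-turn, no divergence
    double alpha = 0.0;          // accept-stat accumulator
    int n_alpha = 0;
  };

  bool no_uturn(const vec& qm, const vec& pm, const vec& qp, const vec& pp) const {
    double fwd = 0.0, bwd = 0.0;
    for (int i = 0; i < n_; ++i) {
      const double dq = qp[i] - qm[i];
      fwd += dq * minv_[i] * pp[i];
      bwd += dq * minv_[i] * pm[i];
    }
    return fwd >= 0.0 && bwd >= 0.0;
  }

  Tree build_tree(vec q, vec p, vec g, double logu, double dir, int depth,
                  double H0) {
    Tree t;
    if (depth == 0) {
      double lp = leapfrog(q, p, g, dir);
      double H = std::isfinite(lp) ? hamiltonian(lp, p) : -INFINITY;
      t.qm = q; t.pm = p; t.gm = g;
      t.qp = q; t.pp = p; t.gp = g;
      t.qprop = q;
      t.n = (logu <= H) ? 1 : 0;
      t.ok = (logu < H + 1000.0);
      if (!t.ok) diverged_ = true;
      double a = std::exp(std::min(0.0, H - H0));
      if (!std::isfinite(a)) a = 0.0;
      t.alpha = a;
      t.n_alpha = 1;
      return t;
    }
    Tree t1 = build_tree(q, p, g, logu, dir, depth - 1, H0);
    if (!t1.ok) return t1;
    Tree t2 = (dir > 0)
        ? build_tree(t1.qp, t1.pp, t1.gp, logu, dir, depth - 1, H0)
        : build_tree(t1.qm, t1.pm, t1.gm, logu, dir, depth - 1, H0);
    if (dir > 0) { t.qm = t1.qm; t.pm = t1.pm; t.gm = t1.gm;
                   t.qp = t2.qp; t.pp = t2.pp; t.gp = t2.gp; }
    else         { t.qm = t2.qm; t.pm = t2.pm; t.gm = t2.gm;
                   t.qp = t1.qp; t.pp = t1.pp; t.gp = t1.gp; }
    t.n = t1.n + t2.n;
    const double u = unif_rand();
    t.qprop = (t.n > 0 && u < (double)t2.n / std::max(1, t.n)) ? t2.qprop
                                                               : t1.qprop;
    t.ok = t2.ok && no_uturn(t.qm, t.pm, t.qp, t.pp);
    t.alpha = t1.alpha + t2.alpha;
    t.n_alpha = t1.n_alpha + t2.n_alpha;
    return t;
  }

  // one NUTS transition; returns the accept statistic for adaptation
  double transition() {
    diverged_ = false;
    depth_hit_ = false;
    vec p(n_);
    for (int i = 0; i < n_; ++i) p[i] = norm_rand() / std::sqrt(minv_[i]);
    const double H0 = hamiltonian(lp_, p);
    const double logu = H0 - exp_rand();  // log of u ~ U(0, exp(H0))

    vec qm = q_, pm = p, gm = g_, qp = q_, pp = p, gp = g_;
    vec qprop = q_;
    int n_valid = 1;
    bool ok = true;
    double alpha = 0.0;
    int n_alpha = 0;

    for (int depth = 0; ok && depth < opt_.max_treedepth; ++depth) {
      const double dir = (unif_rand() < 0.5) ? -1.0 : 1.0;
      Tree t = (dir > 0) ? build_tree(qp, pp, gp, logu, dir, depth, H0)
                         : build_tree(qm, pm, gm, logu, dir, depth, H0);
      if (dir > 0) { qp = t.qp; pp = t.pp; gp = t.gp; }
      else         { qm = t.qm; pm = t.pm; gm = t.gm; }
      alpha += t.alpha;
      n_alpha += t.n_alpha;
      if (t.ok && t.n > 0 &&
          unif_rand() < (double)t.n / (double)n_valid) {
        qprop = t.qprop;
      }
      n_valid += t.n;
      ok = t.ok && no_uturn(qm, pm, qp, pp);
      if (ok && depth == opt_.max_treedepth - 1) depth_hit_ = true;
    }
    q_ = qprop;
    lp_ = model_.lp_grad(q_.data(), g_.data());
    return (n_alpha > 0) ? alpha / n_alpha : 0.0;
  }
};

}  // namespace nuts

#endif
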