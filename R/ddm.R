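#' Parameters of the simple drift-diffusion model
#'
#' The simple (no trial-to-trial variability) DDM: evidence accumulates
#' from `start_frac * boundary` with mean rate `drift` and within-trial
#' noise SD 1 (the identifiability convention) until absorption at 0 or
#' `boundary`; the observed RT adds the non-decision time `ndt`.
#'
#' @param drift Signed mean evidence rate (units/s).
#' @param boundary Boundary separation (> 0).
#' @param ndt Non-decision time in seconds (>= 0).
#' @param start_frac Relative start point in (0, 1); fixed at 0.5 in all
#'   analyses because motion direction is a fair coin.
#' @return A validated list of class `ddm_params`.
#' @export
ddm_params <- function(drift, boundary, ndt, start_frac = 0.5) {
  stopifnot(is.finite(drift), boundary > 0, ndt >= 0,
            start_frac > 0, start_frac < 1)
  structure(list(drift = drift, boundary = boundary, ndt = ndt,
                 start_frac = start_frac), class = "ddm_params")
}

#' Wiener first-passage-time log density
#'
#' Log density of observing an absorption at the given boundary at time
#' `rt_s`. Uses adaptive switching between the small-time and large-time
#' series expansions (absolute truncation tolerance 1e-12). RTs at or below
#' the non-decision time return `-Inf` by contract rather than erroring, so
#' samplers can reject.
#'
#' @param rt_s Reaction times in seconds (> 0).
#' @param boundary_hit `"upper"` or `"lower"` (recycled).
#' @param params A [ddm_params()] object.
#' @return Numeric vector of log densities.
#' @export
wfpt_log_density <- function(rt_s, boundary_hit, params) {
  stopifnot(all(rt_s > 0))
  up <- as.integer(rep_len(boundary_hit == "upper", length(rt_s)))
  .wfpt_log_density_cpp(rt_s, up, params$drift, params$boundary,
                        params$ndt, params$start_frac)
}

#' Gradient of the WFPT log density
#'
#' Analytic gradient with respect to drift, boundary and non-decision time;
#' the same code path the sampler differentiates through.
#'
#' @inheritParams wfpt_log_density
#' @return Matrix with columns `drift`, `boundary`, `ndt`.
#' @export
wfpt_log_density_grad <- function(rt_s, boundary_hit, params) {
  up <- as.integer(rep_len(boundary_hit == "upper", length(rt_s)))
  g <- .wfpt_log_density_grad_cpp(rt_s, up, params$drift, params$boundary,
                                  params$ndt, params$start_frac)
  colnames(g) <- c("drift", "boundary", "ndt")
  g
}

#' Closed-form upper-boundary absorption probability
#'
#' For Brownian motion with drift v, noise SD 1, boundaries at 0 and a and
#' start z = w * a, the probability of absorbing at the upper boundary is
#' (1 - exp(-2 v z)) / (1 - exp(-2 v a)), with the drift-free limit z / a.
#'
#' @param params A [ddm_params()] object.
#' @return Probability of upper-boundary absorption.
#' @export
choice_probability <- function(params) {
  v <- params$drift
  a <- params$boundary
  w <- params$start_frac
  if (abs(v) < 1e-10) return(w)
  num <- -expm1(-2 * v * w * a)
  den <- -expm1(-2 * v * a)
  # guard the large-|v| regime where both terms saturate
  if (den == 0) return(if (v > 0) 1 else 0)
  p <- num / den
  min(max(p, 0), 1)
}

#' Simulate trials from the simple DDM
#'
#' Euler-Maruyama integration of the diffusion path from
#' `start_frac * boundary` until absorption (default 1 ms steps); the
#' reported RT is the hit time plus the non-decision time. Paths not
#' absorbed within `t_max` are flagged censored.
#'
#' @param params A [ddm_params()] object.
#' @param n Number of trials.
#' @param seed Optional integer seed.
#' @param dt Step size in seconds (<= 0.001 recommended).
#' @param t_max Absorption cap in seconds.
#' @return Data frame with `rt_s`, `boundary_hit` (`"upper"`/`"lower"`),
#'   and `censored`.
#' @export
simulate_trials <- function(params, n = 1L, seed = NULL, dt = 0.001,
                            t_max = 10) {
  if (!is.null(seed)) set.seed(seed)
  r <- .ddm_simulate_cpp(n, params$drift, params$boundary, params$ndt,
                         params$start_frac, dt, t_max)
  data.frame(rt_s = r$rt,
             boundary_hit = ifelse(is.na(r$upper), NA_character_,
                                   ifelse(r$upper == 1L, "upper", "lower")),
             censored = r$censored == 1L)
}

#' WFPT defective cumulative distribution on a grid
#'
#' Numerical (trapezoid) integral of the WFPT density for one boundary,
#' used as the reference curve in simulation cross-checks.
#'
#' @inheritParams wfpt_log_density
#' @param t_grid Decision-time grid (seconds, from just above `ndt`).
#' @param boundary_hit `"upper"` or `"lower"`.
#' @return List with `t`, `density`, `cdf` (defective: asymptotes to the
#'   boundary's absorption probability).
#' @export
wfpt_cdf <- function(params, boundary_hit = "upper",
                     t_grid = seq(1e-4, 10, by = 1e-3) + params$ndt) {
  ld <- wfpt_log_density(t_grid, boundary_hit, params)
  d <- exp(ld)
  dt <- diff(t_grid)
  cdf <- c(0, cumsum(0.5 * (d[-1] + d[-length(d)]) * dt))
  list(t = t_grid, density = d, cdf = cdf)
}
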