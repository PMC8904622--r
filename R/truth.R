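#' Ground-truth parameter set for the synthetic-data generator
#'
#' Collects every generative constant the synthetic cohort emulates:
#' condition-level drift rates and boundary separations, the non-decision
#' time distribution, subject-effect SDs, the regression coefficients tying
#' drift/boundary to symptom scores and neural slopes, the neural-slope
#' regression coefficients per band, and the per-channel effect maps. The
#' defaults encode the planted-effects study conditions: drift increasing
#' with coherence; a negative OCD-score effect on drift confined to the two
#' easiest conditions; a negative OCD-score effect on the beta-band slope in
#' every condition and none on gamma; positive coupling of drift to both
#' aggregate slopes; no worry effects anywhere.
#'
#' @param drift_c Condition-level drift rates (evidence units/s), ascending
#'   coherence order.
#' @param boundary_c Condition-level boundary separations (> 0).
#' @param ndt_mean,ndt_sd Mean and SD (s) of per-subject non-decision time.
#' @param sigma_drift,sigma_boundary SDs of subject-level drift/boundary
#'   deviations.
#' @param drift_padua,drift_worry,drift_gamma,drift_beta Length-6 coefficient
#'   vectors on z-scored covariates entering the drift regression.
#' @param boundary_padua,boundary_worry,boundary_gamma,boundary_beta Same for
#'   the boundary regression.
#' @param neural Per-band regression truth: list with elements `gamma` and
#'   `beta`, each holding `b0` (length 6), `b_padua`, `b_worry` (length 6)
#'   and `sigma_eps` (scalar), on the generator's slope scale (baseline-z
#'   power units per 50 ms, before per-condition standardization).
#' @param channel_scale Peak magnitude of the per-channel effect maps.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(drift_c = seq(0.5, 4.5, length.out = 6),
                         boundary_c = c(1.6, 1.6, 1.5, 1.5, 1.4, 1.4),
                         ndt_mean = 0.35, ndt_sd = 0.05,
                         sigma_drift = 0.3, sigma_boundary = 0.15,
                         drift_padua = c(0, 0, 0, 0, -0.3, -0.3),
                         drift_worry = numeric(6),
                         drift_gamma = rep(0.2, 6),
                         drift_beta = rep(0.2, 6),
                         boundary_padua = numeric(6),
                         boundary_worry = numeric(6),
                         boundary_gamma = numeric(6),
                         boundary_beta = numeric(6),
                         neural = list(
                           gamma = list(b0 = seq(0.6, 1.6, length.out = 6),
                                        b_padua = numeric(6),
                                        b_worry = numeric(6),
                                        sigma_eps = 1),
                           beta = list(b0 = seq(0.6, 1.6, length.out = 6),
                                       b_padua = rep(-0.3, 6),
                                       b_worry = numeric(6),
                                       sigma_eps = 1)),
                         channel_scale = 0.12) {
  stopifnot(length(drift_c) == 6, length(boundary_c) == 6,
            all(boundary_c > 0), ndt_mean > 0, ndt_sd >= 0,
            sigma_drift >= 0, sigma_boundary >= 0)
  for (v in list(drift_padua, drift_worry, drift_gamma, drift_beta,
                 boundary_padua, boundary_worry, boundary_gamma,
                 boundary_beta))
    stopifnot(length(v) == 6, all(is.finite(v)))
  out <- list(drift_c = drift_c, boundary_c = boundary_c,
              ndt_mean = ndt_mean, ndt_sd = ndt_sd,
              sigma_drift = sigma_drift, sigma_boundary = sigma_boundary,
              drift_padua = drift_padua, drift_worry = drift_worry,
              drift_gamma = drift_gamma, drift_beta = drift_beta,
              boundary_padua = boundary_padua,
              boundary_worry = boundary_worry,
              boundary_gamma = boundary_gamma,
              boundary_beta = boundary_beta,
              neural = neural, channel_scale = channel_scale)
  class(out) <- "ground_truth"
  out
}

#' Global-null ground truth
#'
#' Same marginal structure as [ground_truth()] but every planted symptom and
#' neural effect set to zero; used for false-positive-rate checks.
#'
#' @param ... Overrides forwarded to [ground_truth()].
#' @return A `ground_truth` object with all covariate coefficients zero.
#' @export
null_ground_truth <- function(...) {
  gt <- ground_truth(drift_padua = numeric(6), drift_gamma = numeric(6),
                     drift_beta = numeric(6), ...)
  gt$neural$beta$b_padua <- numeric(6)
  gt$neural$gamma$b_padua <- numeric(6)
  gt
}

#' Smooth per-channel effect maps for the band-power generator
#'
#' Gamma effects are positive and peak at posterior/lateral sites; beta
#' effects are negative and peak at parieto-occipital sites; both bands get
#' small opposite-sign frontal effects. Profiles are smooth Gaussian bumps
#' in the layout's 2-D coordinates.
#'
#' @param layout A montage from [channel_layout()].
#' @param band `"gamma"` or `"beta"`.
#' @param scale Peak magnitude (baseline-z power per 50 ms per unit slope).
#' @return Named numeric vector of per-channel effects.
#' @export
channel_effect_map <- function(layout, band = c("gamma", "beta"),
                               scale = 0.12) {
  band <- match.arg(band)
  bump <- function(x0, y0, w) exp(-((layout$x - x0)^2 + (layout$y - y0)^2) / (2 * w^2))
  frontal <- bump(0, 0.85, 0.45)
  eff <- if (band == "gamma") {
    post_lat <- bump(-0.8, -0.55, 0.5) + bump(0.8, -0.55, 0.5) +
      0.8 * bump(0, -0.85, 0.5)
    scale * (post_lat / max(post_lat)) - 0.3 * scale * frontal
  } else {
    po <- bump(0, -0.75, 0.5)
    -scale * (po / max(po)) + 0.3 * scale * frontal
  }
  stats::setNames(eff, layout$name)
}
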