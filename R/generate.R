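#' Generate true per-subject, per-condition neural slopes
#'
#' Realizes the neural-slope regression for each band: the slope of a
#' subject's band-power ramp in condition c equals
#' `b0[c] + b_padua[c] * padua_z + b_worry[c] * worry_z + eps`, with
#' Gaussian noise `eps`. These true slopes drive both the band-power
#' generator and (after per-condition z-scoring) the drift regression when
#' the truth couples drift to neural slopes.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed.
#' @return Array `[subject, condition, band]` with bands gamma, beta;
#'   class `neural_slopes`.
#' @export
generate_neural_slopes <- function(cohort, truth = ground_truth(), seed = 1L) {
  set.seed(seed)
  S <- nrow(cohort)
  pz <- as.numeric(scale(cohort$padua))
  wz <- as.numeric(scale(cohort$worry))
  out <- array(NA_real_, dim = c(S, 6, 2),
               dimnames = list(cohort$subject_id, NULL, c("gamma", "beta")))
  term <- function(co, x) if (co == 0) rep(0, length(x)) else co * x
  for (band in c("gamma", "beta")) {
    tr <- truth$neural[[band]]
    for (cc in 1:6) {
      out[, cc, band] <- tr$b0[cc] + term(tr$b_padua[cc], pz) +
        term(tr$b_worry[cc], wz) + rnorm(S, 0, tr$sigma_eps)
      if (anyNA(out[, cc, band]))
        stop("degenerate symptom scores (zero variance) for an active ",
             "neural coefficient")
    }
  }
  class(out) <- c("neural_slopes", class(out))
  out
}

#' Simulate dot-motion behavior from the drift-diffusion model
#'
#' For each subject and coherence condition, drift and boundary are
#' assembled exactly as in the hierarchical regression: condition level plus
#' subject deviation plus coefficient-weighted z-scored covariates (symptom
#' scores, and per-condition-standardized neural slopes when the truth
#' couples them). Choice and RT are then simulated by Euler-Maruyama
#' integration of the diffusion (1 ms steps, within-trial noise SD 1) with
#' the motion direction a fair coin.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param truth A [ground_truth()] object.
#' @param n_trials_per_condition Trials per coherence level (study design:
#'   120).
#' @param coherences The six coherence levels, ascending.
#' @param slopes Optional `neural_slopes` array; required when any
#'   `drift_gamma`/`drift_beta`/`boundary_gamma`/`boundary_beta`
#'   coefficient is nonzero.
#' @param seed Integer seed.
#' @param dt Euler step (s).
#' @return A `TrialTable` data frame: `subject`, `condition`, `coherence`,
#'   `direction` (-1/1), `choice` (-1/1), `rt_s`, `confidence` (1-3).
#' @export
generate_behavior <- function(cohort, truth = ground_truth(),
                              n_trials_per_condition = 120L,
                              coherences = c(0.025, 0.05, 0.15, 0.25,
                                             0.45, 0.7),
                              slopes = NULL, seed = 1L, dt = 0.001) {
  stopifnot(length(coherences) == 6)
  if (any(truth$boundary_c <= 0)) stop("boundary_c must be positive")
  if (any(cohort$true_ndt <= 0)) stop("ndt must be positive")
  neural_on <- any(c(truth$drift_gamma, truth$drift_beta,
                     truth$boundary_gamma, truth$boundary_beta) != 0)
  if (neural_on && is.null(slopes))
    stop("truth couples drift/boundary to neural slopes; supply 'slopes'")
  set.seed(seed)
  S <- nrow(cohort)
  pz <- as.numeric(scale(cohort$padua))
  wz <- as.numeric(scale(cohort$worry))
  gz <- bz <- matrix(0, S, 6)
  if (!is.null(slopes)) {
    gz <- scale(slopes[, , "gamma"])   # z per condition across subjects
    bz <- scale(slopes[, , "beta"])
  }
  res <- vector("list", S * 6)
  k <- 0L
  term <- function(co, x) if (co == 0) 0 else co * x  # inert terms stay 0
  for (s in seq_len(S)) {
    for (cc in 1:6) {
      v <- truth$drift_c[cc] + cohort$true_drift_offset[s] +
        term(truth$drift_padua[cc], pz[s]) +
        term(truth$drift_worry[cc], wz[s]) +
        term(truth$drift_gamma[cc], gz[s, cc]) +
        term(truth$drift_beta[cc], bz[s, cc])
      a <- truth$boundary_c[cc] + cohort$true_boundary_offset[s] +
        term(truth$boundary_padua[cc], pz[s]) +
        term(truth$boundary_worry[cc], wz[s]) +
        term(truth$boundary_gamma[cc], gz[s, cc]) +
        term(truth$boundary_beta[cc], bz[s, cc])
      if (is.na(v) || is.na(a))
        stop("degenerate covariate (zero variance) for an active coefficient")
      if (a <= 0) stop("assembled boundary non-positive for subject ",
                       cohort$subject_id[s], " condition ", cc)
      n <- n_trials_per_condition
      sim <- .ddm_simulate_cpp(n, v, a, cohort$true_ndt[s], 0.5, dt, 10)
      direction <- sample(c(-1L, 1L), n, replace = TRUE)
      correct <- sim$upper == 1L
      # censored (non-absorbed) trials get the RT cap and a random choice
      cen <- sim$censored == 1L
      if (any(cen)) {
        sim$rt[cen] <- 10 + cohort$true_ndt[s]
        correct[cen] <- runif(sum(cen)) < 0.5
      }
      conf_p <- c(0.2, 0.3, 0.5) + c(0.4, 0, -0.4) * (1 - coherences[cc])
      conf <- sample(1:3, n, replace = TRUE, prob = pmax(conf_p, 0.05))
      k <- k + 1L
      res[[k]] <- data.frame(
        subject = cohort$subject_id[s], condition = cc,
        coherence = coherences[cc], direction = direction,
        choice = ifelse(correct, direction, -direction),
        rt_s = sim$rt, confidence = conf, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Generate a normalized band-power tensor with planted ramps
#'
#' Emulates the output of multitaper estimation + log transform + baseline
#' z-normalization + band averaging: per trial, each channel carries
#' baseline-z Gaussian noise plus a linear ramp that starts at stimulus
#' onset (zero through the 200 ms pre-stimulus baseline). The ramp slope is
#' the product of the channel-effect map and the subject/condition true
#' slope, so gamma ramps are positive at posterior/lateral sites and beta
#' ramps negative at parieto-occipital sites.
#'
#' @param cohort,trials,truth The cohort, its `TrialTable`, and the truth.
#' @param layout Montage from [channel_layout()].
#' @param slopes `neural_slopes` from [generate_neural_slopes()].
#' @param band `"gamma"` or `"beta"`.
#' @param time_grid_ms Output time grid (ms); must cover the -200-0 ms
#'   baseline and extend beyond 800 ms.
#' @param noise_sd Per-sample baseline-z noise SD.
#' @param retained_rows Optional row indices of `trials` that survived RT
#'   filtering; other trials are generated but masked out of downstream
#'   aggregation.
#' @param seed Integer seed.
#' @return A `band_power_tensor`: array `[subject, trial, channel, time]`
#'   with attributes `band`, `time_ms`, `baseline_ms`, `trial_rows`
#'   (mapping tensor trials to rows of `trials`) and `retained` (logical
#'   mask of the same shape as `trial_rows`).
#' @export
generate_power <- function(cohort, trials, layout = channel_layout(),
                           truth = ground_truth(), slopes,
                           band = c("gamma", "beta"),
                           time_grid_ms = seq(-200, 1000, by = 50),
                           noise_sd = 1, retained_rows = NULL, seed = 1L) {
  band <- match.arg(band)
  if (min(time_grid_ms) > -200 || max(time_grid_ms) < 800)
    stop("time_grid_ms must cover the -200 ms baseline and reach 800 ms")
  set.seed(seed)
  S <- nrow(cohort)
  eff <- channel_effect_map(layout, band, truth$channel_scale)
  nt <- table(factor(trials$subject, levels = cohort$subject_id))
  if (length(unique(nt)) != 1L)
    stop("all subjects must have the same trial count at generation time")
  Tn <- as.integer(nt[1])
  Ch <- nrow(layout)
  Ti <- length(time_grid_ms)
  ramp <- pmax(time_grid_ms, 0) / 50  # ramp in 50 ms units, 0 in baseline
  pow <- array(NA_real_, dim = c(S, Tn, Ch, Ti),
               dimnames = list(cohort$subject_id, NULL, layout$name, NULL))
  trial_rows <- matrix(NA_integer_, S, Tn)
  for (s in seq_len(S)) {
    rows <- which(trials$subject == cohort$subject_id[s])
    trial_rows[s, ] <- rows
    cond <- trials$condition[rows]
    sl <- slopes[s, , band]
    for (j in seq_len(Tn)) {
      slope_ct <- eff * sl[cond[j]]                 # per-channel slope
      pow[s, j, , ] <- outer(slope_ct, ramp) +
        matrix(rnorm(Ch * Ti, 0, noise_sd), Ch, Ti)
    }
  }
  retained <- if (is.null(retained_rows)) {
    matrix(TRUE, S, Tn)
  } else {
    matrix(trial_rows %in% retained_rows, S, Tn)
  }
  structure(pow, band = band, time_ms = time_grid_ms,
            baseline_ms = c(-200, 0), trial_rows = trial_rows,
            retained = retained,
            class = c("band_power_tensor", "array"))
}

#' Generate raw epoched oscillations with ramped envelopes
#'
#' Produces band-limited oscillations whose amplitude envelope ramps with
#' each trial's true slope, plus broadband noise, for end-to-end testing of
#' the multitaper stage. Power (envelope squared) grows linearly after
#' stimulus onset at the planted per-channel rate and is flat in the
#' baseline.
#'
#' @param n_trials Number of epochs.
#' @param channel_slopes Named per-channel power slopes (baseline-power
#'   fraction per 50 ms; 0 gives a flat envelope).
#' @param band Frequency range `c(lo, hi)` in Hz for the carrier;
#'   must lie below Nyquist.
#' @param sampling_rate Hz (>= 250).
#' @param epoch_ms Epoch extent `c(start, end)` in ms relative to stimulus.
#' @param carrier_hz Optional fixed carrier frequency; default draws one per
#'   trial uniformly in `band`.
#' @param amp Baseline oscillation amplitude.
#' @param noise_sd Broadband noise SD.
#' @param seed Integer seed.
#' @return List with `signal` array `[channel, time, trial]` and `times_ms`.
#' @export
generate_raw_oscillations <- function(n_trials, channel_slopes,
                                      band = c(32, 100), sampling_rate = 500,
                                      epoch_ms = c(-450, 1050),
                                      carrier_hz = NULL, amp = 1,
                                      noise_sd = 0.2, seed = 1L) {
  if (sampling_rate < 250) stop("sampling_rate must be >= 250 Hz")
  if (max(band) >= sampling_rate / 2)
    stop("band exceeds the Nyquist frequency")
  set.seed(seed)
  times <- seq(epoch_ms[1], epoch_ms[2], by = 1000 / sampling_rate)
  Ch <- length(channel_slopes)
  sig <- array(0, dim = c(Ch, length(times), n_trials),
               dimnames = list(names(channel_slopes), NULL, NULL))
  ramp <- pmax(times, 0) / 50
  for (tr in seq_len(n_trials)) {
    f <- if (is.null(carrier_hz)) runif(1, band[1], band[2]) else carrier_hz
    phase <- runif(1, 0, 2 * pi)
    carrier <- sin(2 * pi * f * times / 1000 + phase)
    for (ch in seq_len(Ch)) {
      env <- amp * sqrt(pmax(1 + channel_slopes[ch] * ramp, 0.05))
      sig[ch, , tr] <- env * carrier +
        rnorm(length(times), 0, noise_sd)
    }
  }
  list(signal = sig, times_ms = times)
}
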