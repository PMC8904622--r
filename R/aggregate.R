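#' Difficulty labels for the electrode-weighting regression
#'
#' Trials in the two lowest-coherence conditions (0.025, 0.05) are labeled
#' hard (0), the two highest (0.45, 0.7) easy (1), and the middle two are
#' excluded (NA).
#'
#' @param trials A `TrialTable`.
#' @return Integer vector (0/1/NA) aligned to the rows of `trials`.
#' @export
difficulty_labels <- function(trials) {
  lab <- rep(NA_integer_, nrow(trials))
  lab[trials$condition %in% c(1, 2)] <- 0L
  lab[trials$condition %in% c(5, 6)] <- 1L
  lab
}

#' Per-subject analysis time point: median hard-trial RT
#'
#' The median reaction time over a subject's hard trials (midpoint
#' convention for even counts), snapped to the nearest point of the power
#' time grid.
#'
#' @param trials A `TrialTable` for one or more subjects.
#' @param time_grid_ms Power time grid (ms).
#' @return Named vector of snapped time points (ms) per subject.
#' @export
median_hard_rt <- function(trials, time_grid_ms) {
  subjects <- sort(unique(trials$subject))
  out <- vapply(subjects, function(s) {
    hard <- trials$rt_s[trials$subject == s & trials$condition %in% c(1, 2)]
    if (!length(hard)) stop("subject ", s, " has no hard trials")
    md <- median(hard) * 1000
    time_grid_ms[which.min(abs(time_grid_ms - md))]
  }, numeric(1))
  stats::setNames(out, subjects)
}

#' Multi-level logistic electrode weighting
#'
#' Bayesian hierarchical logistic regression predicting trial difficulty
#' (easy = 1 vs hard = 0) from band power at all electrodes, evaluated at
#' each subject's median hard-trial RT. Channel predictors are standardized
#' before fitting; coefficients get weakly informative Normal(0, 2.5)
#' priors and per-subject coefficients partially pool toward per-channel
#' group means. Subjects with a single label class are dropped with a
#' warning.
#'
#' @param power A `band_power_tensor` (see [generate_power()]).
#' @param trials The `TrialTable` the tensor was generated from (aligned
#'   through the tensor's `trial_rows` attribute).
#' @param chains,warmup,iter,seed,max_treedepth MCMC configuration
#'   (defaults 4 chains, 1000 warmup, 3000 retained).
#' @return An `electrode_weights` object: `posterior_draws` over the group
#'   structure (per-channel means `w[...]`, SDs `tau[...]`, intercepts),
#'   plus channel names, per-channel standardization scales and the
#'   per-subject time points used.
#' @export
fit_electrode_weights <- function(power, trials, chains = 4L,
                                  warmup = 1000L, iter = 3000L, seed = 1L,
                                  max_treedepth = 10L) {
  times <- attr(power, "time_ms")
  trial_rows <- attr(power, "trial_rows")
  channels <- dimnames(power)[[3]]
  subjects <- dimnames(power)[[1]]
  tstar <- median_hard_rt(trials[trials$subject %in% subjects, ], times)
  X <- list(); y <- list(); sidx <- list()
  keep_subj <- character(0)
  retained <- attr(power, "retained")
  if (is.null(retained)) retained <- matrix(TRUE, length(subjects),
                                            ncol(trial_rows))
  for (s in seq_along(subjects)) {
    rows <- trial_rows[s, ]
    lab <- difficulty_labels(trials[rows, , drop = FALSE])
    use <- which(!is.na(lab) & retained[s, ])
    if (length(unique(lab[use])) < 2) {
      warning("subject ", subjects[s], " has a single label class; dropped")
      next
    }
    ti <- which(times == tstar[subjects[s]])
    keep_subj <- c(keep_subj, subjects[s])
    X[[length(X) + 1]] <- power[s, use, , ti]
    y[[length(y) + 1]] <- lab[use]
    sidx[[length(sidx) + 1]] <- rep(length(keep_subj) - 1L, length(use))
  }
  if (length(keep_subj) < 2) stop("need at least 2 usable subjects")
  X <- do.call(rbind, X)
  y <- unlist(y)
  sidx <- unlist(sidx)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(!is.finite(scl) | scl == 0))
    stop("zero-variance channel predictor")
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  set.seed(seed)
  fit <- .fit_logistic_cpp(Xs, as.integer(y), as.integer(sidx),
                           length(keep_subj), chains, warmup, iter,
                           max_treedepth)
  nm <- c("alpha0", "sigma_alpha", "tau", paste0("w[", channels, "]"),
          paste0("alpha[", keep_subj, "]"))
  pd <- .as_posterior_draws(fit, iter, nm, seed, warmup)
  if (!pd$converged)
    warning("electrode weighting flagged non-converged: max split R-hat = ",
            signif(pd$max_rhat, 4))
  structure(list(draws = pd, channels = channels, center = ctr,
                 scale = scl, subjects = keep_subj, time_points = tstar),
            class = "electrode_weights")
}

#' Extract the group-level channel coefficient draws
#'
#' @param weights An `electrode_weights` object.
#' @return Draws x channel matrix of group-level logistic coefficients.
#' @export
weight_draws <- function(weights) {
  m <- draws_matrix(weights$draws)
  m[, paste0("w[", weights$channels, "]"), drop = FALSE]
}

#' Apply electrode weights to a band-power tensor
#'
#' For each posterior draw, the aggregate time course is the
#' coefficient-weighted sum of channel power (intercepts excluded),
#' averaged first across trials within subject and condition. Because the
#' weights were estimated on standardized predictors, channel power is
#' divided by the training scale before weighting. The aggregate is linear
#' in the power tensor.
#'
#' @param weights An `electrode_weights` object (or a draws x channel
#'   matrix of coefficients).
#' @param power A `band_power_tensor` with matching channel axis.
#' @param trials The `TrialTable` backing the tensor.
#' @param n_draws Optional subsample of posterior draws (default: all).
#' @param seed Seed for the draw subsample.
#' @return An `aggregate_timecourse`: array
#'   `[draw, subject, condition, time]` with `time_ms` attribute.
#' @export
apply_weights <- function(weights, power, trials, n_draws = NULL,
                          seed = 1L) {
  W <- if (inherits(weights, "electrode_weights")) weight_draws(weights)
       else as.matrix(weights)
  channels <- dimnames(power)[[3]]
  wch <- sub("^w\\[(.*)\\]$", "\\1", colnames(W))
  if (!is.null(colnames(W))) {
    if (!all(channels %in% wch))
      stop("channel mismatch between weights and power tensor")
    W <- W[, match(channels, wch), drop = FALSE]
  } else if (ncol(W) != length(channels)) {
    stop("channel mismatch between weights and power tensor")
  }
  if (inherits(weights, "electrode_weights"))
    W <- sweep(W, 2, weights$scale[match(channels, weights$channels)], "/")
  if (!is.null(n_draws) && n_draws < nrow(W)) {
    set.seed(seed)
    W <- W[sort(sample(nrow(W), n_draws)), , drop = FALSE]
  }
  times <- attr(power, "time_ms")
  subjects <- dimnames(power)[[1]]
  trial_rows <- attr(power, "trial_rows")
  S <- length(subjects); Ti <- length(times)
  conds <- 1:6
  # mean power per subject x condition x channel x time (aggregation is
  # linear, so trial-averaging before weighting is exact)
  retained <- attr(power, "retained")
  if (is.null(retained)) retained <- matrix(TRUE, S, ncol(trial_rows))
  mp <- array(NA_real_, c(S, 6, length(channels), Ti))
  for (s in seq_len(S)) {
    cond <- trials$condition[trial_rows[s, ]]
    for (cc in conds) {
      j <- which(cond == cc & retained[s, ])
      if (!length(j)) next
      mp[s, cc, , ] <- apply(power[s, j, , , drop = FALSE], c(3, 4), mean)
    }
  }
  flat <- matrix(aperm(mp, c(3, 1, 2, 4)), nrow = length(channels))
  agg <- W %*% flat  # draws x (S*6*Ti)
  out <- array(agg, dim = c(nrow(W), S, 6, Ti),
               dimnames = list(NULL, subjects, NULL, NULL))
  structure(out, time_ms = times,
            class = c("aggregate_timecourse", "array"))
}

#' Ramp-slope statistic of the aggregate time course
#'
#' The mean of the consecutive 50 ms increments of the aggregate over the
#' 500 ms period from 300 to 800 ms, which telescopes to
#' (y(800) - y(300)) / 10. Computed per draw, subject and condition; the
#' point value per subject/condition is the median of the marginal
#' posterior.
#'
#' @param aggregate An `aggregate_timecourse` (or an array
#'   `[draw, subject, condition, time]` with a `time_ms` attribute).
#' @param from,to,by Slope window and increment (ms).
#' @return List with `draws` (`[draw, subject, condition]`) and `point`
#'   (subject x condition matrix of marginal medians).
#' @export
slope_statistic <- function(aggregate, from = 300, to = 800, by = 50) {
  times <- attr(aggregate, "time_ms")
  need <- seq(from, to, by = by)
  idx <- match(need, times)
  if (anyNA(idx))
    stop("time grid is missing required points: ",
         paste(need[is.na(idx)], collapse = ", "))
  nstep <- length(need) - 1
  y0 <- aggregate[, , , idx[1], drop = FALSE]
  y1 <- aggregate[, , , idx[length(idx)], drop = FALSE]
  sl <- (y1 - y0) / nstep
  dim(sl) <- dim(aggregate)[1:3]
  dimnames(sl) <- dimnames(aggregate)[1:3]
  point <- apply(sl, c(2, 3), median)
  rownames(point) <- dimnames(aggregate)[[2]]
  list(draws = sl, point = point)
}

#' Scalp projection of the aggregate measure
#'
#' For each subject, the channels x time matrix of mean power X is
#' projected on the aggregate time course Y (one column per draw):
#' column j of X Y is normalized by the squared norm of Y's column j,
#' i.e. the slope of the least-squares regression of each channel on the
#' aggregate through the origin. Values are averaged across subjects and
#' the median across draws is reported per channel.
#'
#' @param power A `band_power_tensor`.
#' @param aggregate The matching `aggregate_timecourse`.
#' @param trials The backing `TrialTable`.
#' @return Named per-channel projection vector (attribute `draws` holds the
#'   subject-mean projection per draw).
#' @export
scalp_projection <- function(power, aggregate, trials) {
  times <- attr(power, "time_ms")
  channels <- dimnames(power)[[3]]
  subjects <- dimnames(power)[[1]]
  trial_rows <- attr(power, "trial_rows")
  retained <- attr(power, "retained")
  if (is.null(retained)) retained <- matrix(TRUE, length(subjects),
                                            ncol(trial_rows))
  nd <- dim(aggregate)[1]
  acc <- array(0, c(length(channels), nd))
  for (s in seq_along(subjects)) {
    j <- which(retained[s, ])
    Xs <- apply(power[s, j, , , drop = FALSE], c(3, 4), mean)  # ch x time
    Ys <- t(apply(aggregate[, s, , , drop = FALSE], c(1, 4), mean))
    # Ys: time x draw
    num <- Xs %*% Ys                      # ch x draw
    den <- colSums(Ys^2)
    bad <- den == 0
    if (any(bad)) {
      warning("zero-norm aggregate column for ", sum(bad),
              " draw(s); projection undefined there")
      den[bad] <- NA_real_
    }
    acc <- acc + sweep(num, 2, den, "/")
  }
  proj <- acc / length(subjects)
  out <- apply(proj, 1, median, na.rm = TRUE)
  names(out) <- channels
  attr(out, "draws") <- proj
  out
}
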