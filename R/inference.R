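#' Offset-from-first ("primed") reparameterization
#'
#' To reduce posterior correlation, condition-level locations and each
#' regression-coefficient block are sampled as a first-condition value plus
#' per-condition offsets: `x[1] = x'[1]`, `x[k] = x'[1] + x'[k]` for
#' `k >= 2`. `cumulative_transform` maps primed to natural parameters;
#' `cumulative_inverse` is its exact inverse.
#'
#' @param x Numeric vector of 6 values.
#' @return Numeric vector of 6 values.
#' @export
cumulative_transform <- function(x) {
  stopifnot(length(x) == 6)
  c(x[1], x[1] + x[-1])
}

#' @rdname cumulative_transform
#' @export
cumulative_inverse <- function(x) {
  stopifnot(length(x) == 6)
  c(x[1], x[-1] - x[1])
}

#' Assemble a subject/condition drift (or boundary) from its regression
#'
#' The exact linear combination used both by the generator and inside the
#' sampler: condition level + subject deviation + coefficient-weighted
#' z-scored covariates.
#'
#' @param condition_level Condition-level location.
#' @param subject_effect Subject deviation.
#' @param coefficients Named list/vector with entries `padua`, `worry`,
#'   `gamma`, `beta` (missing entries are treated as inactive).
#' @param covariates Named list/vector of standardized covariate values for
#'   this subject/condition; every active coefficient must have a matching
#'   covariate.
#' @return The assembled scalar.
#' @export
assemble_drift <- function(condition_level, subject_effect = 0,
                           coefficients = list(), covariates = list()) {
  out <- condition_level + subject_effect
  for (nm in names(coefficients)) {
    co <- coefficients[[nm]]
    if (is.null(co) || co == 0) next
    if (is.null(covariates[[nm]]))
      stop("coefficient '", nm, "' is active but covariate is missing")
    out <- out + co * covariates[[nm]]
  }
  out
}

#' Specification of the drift-diffusion regression variant
#'
#' @param variant One of `"behavior_only"` (no covariates), `"symptoms"`
#'   (symptom scores only), `"neural"` (neural slopes only), or `"full"`
#'   (both covariate blocks).
#' @return List of class `model_spec` with logical flags `has_symptoms`,
#'   `has_neural`.
#' @export
model_spec <- function(variant = c("behavior_only", "symptoms", "neural",
                                   "full")) {
  variant <- match.arg(variant)
  structure(list(variant = variant,
                 has_symptoms = variant %in% c("symptoms", "full"),
                 has_neural = variant %in% c("neural", "full")),
            class = "model_spec")
}

.ddm_param_names <- function(S, subjects, has_sym, has_neu) {
  cn <- function(stem) paste0(stem, "_c", 1:6)
  nm <- c(cn("drift"), cn("boundary"),
          "mu_ndt", "sigma_ndt", "sigma_drift", "sigma_boundary",
          paste0("ndt[", subjects, "]"),
          paste0("drift_s[", subjects, "]"),
          paste0("boundary_s[", subjects, "]"))
  if (has_sym) nm <- c(nm, cn("drift_padua"), cn("drift_worry"),
                       cn("boundary_padua"), cn("boundary_worry"))
  if (has_neu) nm <- c(nm, cn("drift_gamma"), cn("drift_beta"),
                       cn("boundary_gamma"), cn("boundary_beta"))
  nm
}

.as_posterior_draws <- function(fit, iter, param_names, seed, warmup) {
  chains <- fit$chains
  arr <- array(NA_real_, dim = c(length(chains), iter, length(param_names)),
               dimnames = list(NULL, NULL, param_names))
  for (ch in seq_along(chains)) arr[ch, , ] <- chains[[ch]]
  diag <- diagnose_array(arr)
  flagged <- any(diag$rhat > 1.05, na.rm = TRUE) || any(is.na(diag$rhat))
  structure(list(draws = arr, diagnostics = diag,
                 max_rhat = suppressWarnings(max(diag$rhat, na.rm = TRUE)),
                 converged = !flagged,
                 divergences = sum(fit$divergences),
                 treedepth_hits = sum(fit$treedepth_hits),
                 stepsize = fit$stepsize,
                 meta = list(seed = seed, warmup = warmup, iter = iter,
                             chains = length(chains))),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("posterior_draws:", d[1], "chains x", d[2], "iterations x", d[3],
      "parameters\n")
  cat(sprintf("max split R-hat: %.4f (%s); divergences: %d\n",
              x$max_rhat, if (x$converged) "converged" else "FLAGGED",
              x$divergences))
  invisible(x)
}

#' Flatten posterior draws to a draws x parameter matrix
#'
#' @param x A `posterior_draws` object.
#' @return Matrix with one column per parameter, chains stacked.
#' @export
draws_matrix <- function(x) {
  d <- dim(x$draws)
  m <- matrix(aperm(x$draws, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(m) <- dimnames(x$draws)[[3]]
  m
}

#' Fit the hierarchical drift-diffusion regression model
#'
#' Gradient-based MCMC (No-U-Turn sampler) on the exact Wiener
#' first-passage-time likelihood. Condition-level drift rates and boundary
#' separations, a shared per-subject non-decision time, partial pooling of
#' subject drift/boundary deviations, and (depending on the variant)
#' regression of both drift and boundary on z-scored symptom scores and
#' per-condition-standardized neural slopes. Priors: Normal(0, 20) on all
#' primed locations and coefficients except the first boundary location
#' Normal(1, 20); non-decision group mean Normal(0.5, 1) s and group SD
#' half-Normal(0, 1); subject-effect SDs half-Normal(0, 20). The start
#' point is fixed at 0.5.
#'
#' Convergence failures (any split R-hat > 1.05) flag the fit rather than
#' abort it.
#'
#' @param trials A filtered `TrialTable`.
#' @param variant Model variant; see [model_spec()].
#' @param covariates For variants with covariates: list with `scores` (data
#'   frame containing `subject`, `padua_z`, `worry_z`) and, for neural
#'   variants, `gamma_z` and `beta_z` (subject x condition matrices,
#'   z-scored per condition), as produced by [zscore_covariates()].
#' @param chains,warmup,iter MCMC configuration (defaults 4 chains, 1000
#'   warmup, 3000 retained per chain).
#' @param seed Integer seed; identical seed and data give identical draws.
#' @param max_treedepth NUTS tree-depth cap.
#' @param ndt_ub_frac Non-decision time is sampled inside
#'   `(0, ndt_ub_frac * min RT)` per subject via a scaled logit.
#' @return A `posterior_draws` object with diagnostics attached.
#' @export
fit_ddm <- function(trials, variant = "behavior_only", covariates = NULL,
                    chains = 4L, warmup = 1000L, iter = 3000L, seed = 1L,
                    max_treedepth = 10L, ndt_ub_frac = 0.999) {
  spec <- model_spec(variant)
  subjects <- sort(unique(trials$subject))
  S <- length(subjects)
  if (S < 2) stop("need at least 2 subjects")
  sidx <- match(trials$subject, subjects) - 1L
  cidx <- as.integer(trials$condition) - 1L
  stopifnot(all(cidx >= 0), all(cidx < 6))
  correct <- as.integer(trials$choice == trials$direction)

  padua <- worry <- numeric(S)
  gam <- bet <- matrix(0, S, 6)
  if (spec$has_symptoms || spec$has_neural) {
    if (is.null(covariates)) stop("variant '", spec$variant,
                                  "' requires covariates")
    if (spec$has_symptoms) {
      sc <- covariates$scores
      m <- match(subjects, sc$subject)
      if (anyNA(m)) stop("missing symptom scores for some subjects")
      padua <- sc$padua_z[m]
      worry <- sc$worry_z[m]
    }
    if (spec$has_neural) {
      if (is.null(covariates$gamma_z) || is.null(covariates$beta_z))
        stop("variant '", spec$variant, "' requires gamma_z and beta_z")
      gam <- as.matrix(covariates$gamma_z)
      bet <- as.matrix(covariates$beta_z)
      if (!is.null(rownames(gam))) gam <- gam[match(subjects, rownames(gam)), ]
      if (!is.null(rownames(bet))) bet <- bet[match(subjects, rownames(bet)), ]
      if (anyNA(gam) || anyNA(bet)) stop("missing neural slopes")
    }
  }
  set.seed(seed)
  fit <- .fit_ddm_cpp(sidx, cidx, trials$rt_s, correct, S, padua, worry,
                      gam, bet, spec$has_symptoms, spec$has_neural,
                      chains, warmup, iter, max_treedepth, ndt_ub_frac)
  nm <- .ddm_param_names(S, subjects, spec$has_symptoms, spec$has_neural)
  out <- .as_posterior_draws(fit, iter, nm, seed, warmup)
  out$meta$variant <- spec$variant
  out$meta$subjects <- subjects
  if (!out$converged)
    warning("fit flagged non-converged: max split R-hat = ",
            signif(out$max_rhat, 4))
  out
}

#' Fit the neural-slope regression on symptom scores
#'
#' Per-condition Gaussian regression of (per-condition z-scored) aggregate
#' slopes on z-scored Padua and worry scores, with intercepts pooled
#' hierarchically across conditions: `b0[c] ~ Normal(b_mu0, b_sigma0)` with
#' Normal(0, 20) hyperpriors, Normal(0, 20) coefficient priors and
#' half-Normal(0, 20) noise-SD priors.
#'
#' @param slopes_z Subject x condition matrix of slopes, z-scored per
#'   condition (NAs allowed and treated as missing).
#' @param scores Data frame with `subject` (optional), `padua_z`,
#'   `worry_z` aligned to the rows of `slopes_z`.
#' @param chains,warmup,iter,seed,max_treedepth MCMC configuration.
#' @return A `posterior_draws` object with parameters `b0_c*`,
#'   `b_padua_c*`, `b_worry_c*`, `sigma_eps_c*`, `b_mu0`, `b_sigma0`.
#' @export
fit_neural_regression <- function(slopes_z, scores, chains = 4L,
                                  warmup = 1000L, iter = 3000L, seed = 1L,
                                  max_treedepth = 10L) {
  slopes_z <- as.matrix(slopes_z)
  S <- nrow(slopes_z)
  if (S < 3) stop("need at least 3 subjects")
  stopifnot(nrow(scores) == S)
  observed <- is.finite(slopes_z)
  y <- ifelse(observed, slopes_z, 0)
  set.seed(seed)
  fit <- .fit_gauss_cpp(y, observed, scores$padua_z, scores$worry_z,
                        chains, warmup, iter, max_treedepth)
  nm <- c("b_mu0", "b_sigma0", paste0("b0_c", 1:6),
          paste0("b_padua_c", 1:6), paste0("b_worry_c", 1:6),
          paste0("sigma_eps_c", 1:6))
  out <- .as_posterior_draws(fit, iter, nm, seed, warmup)
  if (!out$converged)
    warning("fit flagged non-converged: max split R-hat = ",
            signif(out$max_rhat, 4))
  out
}

#' Split R-hat and effective sample size diagnostics
#'
#' Split R-hat compares within- and between-half-chain variance (each chain
#' is split in half); the effective sample size uses the combined-chain
#' autocorrelation series with Geyer's initial-positive-sequence
#' truncation. Parameters constant across all draws have undefined R-hat
#' and are returned as NA (flagged).
#'
#' @param draws A `posterior_draws` object or a `chains x iter x parameter`
#'   array (at least 2 chains).
#' @return Data frame with `parameter`, `rhat`, `ess`.
#' @export
diagnose <- function(draws) {
  if (inherits(draws, "posterior_draws")) return(draws$diagnostics)
  diagnose_array(draws)
}

diagnose_array <- function(arr) {
  stopifnot(length(dim(arr)) == 3)
  if (dim(arr)[1] < 2) stop("need at least 2 chains")
  P <- dim(arr)[3]
  nm <- dimnames(arr)[[3]]
  if (is.null(nm)) nm <- paste0("par", seq_len(P))
  out <- data.frame(parameter = nm, rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (p in seq_len(P)) {
    x <- arr[, , p, drop = FALSE]
    dim(x) <- dim(arr)[1:2]
    out$rhat[p] <- split_rhat(x)
    out$ess[p] <- ess_mean(x)
  }
  out
}

#' @rdname diagnose
#' @param chains_matrix Chains x iterations matrix for one parameter.
#' @export
split_rhat <- function(chains_matrix) {
  m <- nrow(chains_matrix)
  n <- floor(ncol(chains_matrix) / 2)
  halves <- rbind(chains_matrix[, seq_len(n), drop = FALSE],
                  chains_matrix[, n + seq_len(n), drop = FALSE])
  mu <- rowMeans(halves)
  vars <- apply(halves, 1, var)
  W <- mean(vars)
  B <- n * var(mu)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_mean <- function(chains_matrix) {
  m <- nrow(chains_matrix)
  n <- ncol(chains_matrix)
  W <- mean(apply(chains_matrix, 1, var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * var(rowMeans(chains_matrix))
  varplus <- (n - 1) / n * W + B / n
  # combined autocovariance via per-chain acf
  max_lag <- min(n - 1, 1000)
  acov <- matrix(0, m, max_lag + 1)
  for (i in seq_len(m)) {
    a <- stats::acf(chains_matrix[i, ], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)
    acov[i, ] <- a$acf[, 1, 1]
  }
  rho <- 1 - (W - colMeans(acov)[-1]) / varplus
  # Geyer initial positive sequence on paired sums
  np <- floor(length(rho) / 2)
  if (np == 0) return(m * n)
  psum <- rho[2 * seq_len(np) - 1] + rho[2 * seq_len(np)]
  K <- which(psum <= 0)
  K <- if (length(K)) K[1] - 1 else np
  tau <- 1 + 2 * sum(rho[seq_len(max(0, 2 * K))])
  max(m * n / max(tau, 1e-10), 1)
}
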