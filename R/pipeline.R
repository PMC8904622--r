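#' Study configuration
#'
#' Captures every analysis constant in one place: cohort design, trial
#' counts, RT filter bounds, band definitions and time grid, MCMC
#' configuration per stage, the posterior-draw subsample used for
#' weighting, and the master seed from which every stage seed derives.
#' Defaults are the full study conditions; tests and examples pass smaller
#' sizes.
#'
#' @param n_subjects,bin_targets Cohort design (see [generate_cohort()]).
#' @param n_trials_per_condition Trials per coherence level.
#' @param truth The generative [ground_truth()].
#' @param min_rt,max_rt RT filter bounds (s).
#' @param time_grid_ms Power time grid (ms).
#' @param mcmc_ddm,mcmc_logistic,mcmc_neural Per-stage lists with `chains`,
#'   `warmup`, `iter`.
#' @param draws_subsample Posterior draws carried through the weighting
#'   stage (NULL = all).
#' @param exclude_frontal Run the EEG stages on the 48 non-frontal
#'   channels.
#' @param keep_tensors Keep the band-power tensors in the result bundle.
#' @param seed Master integer seed.
#' @return List of class `study_config`.
#' @export
study_config <- function(n_subjects = 67L,
                         bin_targets = c(19L, 18L, 15L, 15L),
                         n_trials_per_condition = 120L,
                         truth = ground_truth(),
                         min_rt = 0.25, max_rt = 10,
                         time_grid_ms = seq(-200, 1000, by = 50),
                         mcmc_ddm = list(chains = 4L, warmup = 1000L,
                                         iter = 3000L),
                         mcmc_logistic = list(chains = 4L, warmup = 1000L,
                                              iter = 3000L),
                         mcmc_neural = list(chains = 4L, warmup = 1000L,
                                            iter = 3000L),
                         draws_subsample = 500L,
                         exclude_frontal = FALSE,
                         keep_tensors = FALSE,
                         seed = 1L) {
  structure(as.list(environment()), class = "study_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes, in order: cohort and ground-truth realization, DDM behavior
#' simulation, RT filtering, band-power generation for both bands,
#' electrode weighting, aggregation, slope extraction, covariate
#' standardization, the neural-slope regressions, the reduced
#' (symptoms-only) and full drift-diffusion regression fits, and the
#' summaries, condition contrasts and full-versus-reduced coefficient
#' changes. Every stage seed derives from the master seed, so a rerun with
#' the same config is numerically identical.
#'
#' @param config A [study_config()].
#' @return A result bundle (list) with the stage outputs, effect summaries
#'   and a `manifest` recording seeds, stage completion and convergence
#'   diagnostics.
#' @export
run_pipeline <- function(config = study_config()) {
  t0 <- Sys.time()
  seeds <- config$seed + c(cohort = 101L, slopes = 211L, behavior = 307L,
                           pow_gamma = 401L, pow_beta = 409L,
                           w_gamma = 503L, w_beta = 509L, eq2 = 601L,
                           ddm_red = 701L, ddm_full = 709L, med = 801L)
  manifest <- list(seed = config$seed, seeds = as.list(seeds),
                   stages = character(0), diagnostics = list(),
                   package_version = as.character(utils::packageVersion("driftband")))
  stage <- function(nm) manifest$stages <<- c(manifest$stages, nm)

  truth <- config$truth
  layout <- channel_layout()
  if (config$exclude_frontal) layout_use <- exclude_frontal(layout)
  else layout_use <- layout

  cohort <- generate_cohort(config$n_subjects, config$bin_targets, truth,
                            seed = seeds["cohort"])
  stage("cohort")
  slopes_true <- generate_neural_slopes(cohort, truth, seed = seeds["slopes"])
  stage("neural_slopes")
  trials <- generate_behavior(cohort, truth,
                              n_trials_per_condition =
                                config$n_trials_per_condition,
                              slopes = slopes_true,
                              seed = seeds["behavior"])
  stage("behavior")
  filt <- filter_trials(trials, config$min_rt, config$max_rt)
  stage("filter")

  pw <- list()
  wts <- list()
  agg <- list()
  slope_point <- list()
  slope_draws <- list()
  proj <- list()
  for (band in c("gamma", "beta")) {
    p <- generate_power(cohort, trials, layout_use, truth, slopes_true,
                        band = band, time_grid_ms = config$time_grid_ms,
                        retained_rows =
                          which(trials$rt_s >= config$min_rt &
                                trials$rt_s <= config$max_rt),
                        seed = seeds[paste0("pow_", band)])
    w <- fit_electrode_weights(p, trials,
                               chains = config$mcmc_logistic$chains,
                               warmup = config$mcmc_logistic$warmup,
                               iter = config$mcmc_logistic$iter,
                               seed = seeds[paste0("w_", band)])
    a <- apply_weights(w, p, trials, n_draws = config$draws_subsample,
                       seed = seeds[paste0("w_", band)] + 1L)
    sl <- slope_statistic(a)
    proj[[band]] <- scalp_projection(p, a, trials)
    wts[[band]] <- w
    agg[[band]] <- a
    slope_point[[band]] <- sl$point
    slope_draws[[band]] <- sl$draws
    manifest$diagnostics[[paste0("weights_", band)]] <-
      list(max_rhat = w$draws$max_rhat, converged = w$draws$converged)
    if (config$keep_tensors) pw[[band]] <- p
    stage(paste0("power_", band))
  }

  scores <- data.frame(subject = cohort$subject_id,
                       padua_raw = cohort$padua, worry_raw = cohort$worry,
                       stringsAsFactors = FALSE)
  zc <- zscore_covariates(scores, slopes = slope_point)
  stage("standardize")

  eq2 <- list()
  for (band in c("gamma", "beta")) {
    eq2[[band]] <- fit_neural_regression(zc$slopes_z[[band]], zc$scores,
                                         chains = config$mcmc_neural$chains,
                                         warmup = config$mcmc_neural$warmup,
                                         iter = config$mcmc_neural$iter,
                                         seed = seeds["eq2"] +
                                           (band == "beta"))
    manifest$diagnostics[[paste0("eq2_", band)]] <-
      list(max_rhat = eq2[[band]]$max_rhat,
           converged = eq2[[band]]$converged)
  }
  stage("neural_regression")

  cov_sym <- list(scores = zc$scores)
  cov_full <- list(scores = zc$scores, gamma_z = zc$slopes_z$gamma,
                   beta_z = zc$slopes_z$beta)
  fit_red <- fit_ddm(filt$trials, "symptoms", cov_sym,
                     chains = config$mcmc_ddm$chains,
                     warmup = config$mcmc_ddm$warmup,
                     iter = config$mcmc_ddm$iter, seed = seeds["ddm_red"])
  stage("ddm_reduced")
  fit_full <- fit_ddm(filt$trials, "full", cov_full,
                      chains = config$mcmc_ddm$chains,
                      warmup = config$mcmc_ddm$warmup,
                      iter = config$mcmc_ddm$iter, seed = seeds["ddm_full"])
  stage("ddm_full")
  manifest$diagnostics$ddm_reduced <-
    list(max_rhat = fit_red$max_rhat, converged = fit_red$converged)
  manifest$diagnostics$ddm_full <-
    list(max_rhat = fit_full$max_rhat, converged = fit_full$converged)

  summaries <- list(
    drift_padua_reduced = summarize_block(fit_red, "drift_padua"),
    drift_worry_reduced = summarize_block(fit_red, "drift_worry"),
    drift_padua_full = summarize_block(fit_full, "drift_padua"),
    drift_gamma_full = summarize_block(fit_full, "drift_gamma"),
    drift_beta_full = summarize_block(fit_full, "drift_beta"),
    b_padua_gamma = summarize_block(eq2$gamma, "b_padua"),
    b_padua_beta = summarize_block(eq2$beta, "b_padua"),
    b_worry_gamma = summarize_block(eq2$gamma, "b_worry"),
    b_worry_beta = summarize_block(eq2$beta, "b_worry"))
  contrasts <- do.call(rbind, lapply(5:6, function(e)
    do.call(rbind, lapply(1:2, function(h) {
      out <- condition_contrast(fit_red, paste0("drift_padua_c", e),
                                paste0("drift_padua_c", h))
      out$easy <- e; out$hard <- h
      out
    }))))
  mediation <- do.call(rbind, lapply(1:6, function(cc)
    mediation_change(fit_full, fit_red, paste0("drift_padua_c", cc),
                     seed = seeds["med"] + cc)))
  stage("effects")

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$complete <- TRUE
  list(config = config, truth = truth, cohort = cohort,
       slopes_true = slopes_true, trials = trials,
       filter_report = filt$report, power = if (config$keep_tensors) pw,
       weights = wts, aggregate = agg, slope_point = slope_point,
       slope_draws = slope_draws, scalp_projection = proj,
       scores_z = zc$scores, slopes_z = zc$slopes_z, eq2 = eq2,
       fit_reduced = fit_red, fit_full = fit_full,
       summaries = summaries, contrasts = contrasts,
       mediation = mediation, manifest = manifest)
}
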