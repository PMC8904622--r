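# Shared fixture builders. Everything is generated in code at test time;
# sizes are deliberately small so the default run stays fast.

# a behavior-only truth (no symptom or neural coupling) for pure DDM tests
truth_behavior_only <- function(drift_padua = numeric(6), ...) {
  ground_truth(drift_padua = drift_padua, drift_gamma = numeric(6),
               drift_beta = numeric(6), ...)
}

tiny_cohort <- function(n = 6L, truth = truth_behavior_only(), seed = 1L) {
  per <- c(rep(ceiling(n / 4), n %% 4), rep(floor(n / 4), 4 - n %% 4))
  if (n %% 4 == 0) per <- rep(n / 4, 4)
  generate_cohort(n, as.integer(per), truth, seed = seed)
}

tiny_trials <- function(cohort, truth = truth_behavior_only(),
                        n_per_cond = 12L, seed = 2L, slopes = NULL) {
  generate_behavior(cohort, truth, n_trials_per_condition = n_per_cond,
                    slopes = slopes, seed = seed)
}

# hand-built power tensor with a planted per-channel class difference:
# label-1 trials get `separation` added on the planted channel at all
# post-stimulus times
planted_power_tensor <- function(n_subj, n_trials, channels, planted_ch,
                                 separation, trials, seed,
                                 time_ms = seq(-200, 1000, by = 50)) {
  set.seed(seed)
  S <- n_subj
  Ch <- length(channels)
  Ti <- length(time_ms)
  lab <- difficulty_labels(trials)
  pow <- array(rnorm(S * n_trials * Ch * Ti),
               dim = c(S, n_trials, Ch, Ti),
               dimnames = list(unique(trials$subject), NULL, channels, NULL))
  trial_rows <- matrix(seq_len(S * n_trials), S, n_trials, byrow = TRUE)
  post <- which(time_ms > 0)
  for (s in seq_len(S)) {
    rows <- trial_rows[s, ]
    easy <- which(lab[rows] == 1L)
    if (length(easy) && !is.na(planted_ch))
      pow[s, easy, planted_ch, post] <- pow[s, easy, planted_ch, post] +
        separation
  }
  structure(pow, band = "gamma", time_ms = time_ms,
            baseline_ms = c(-200, 0), trial_rows = trial_rows,
            retained = matrix(TRUE, S, n_trials),
            class = c("band_power_tensor", "array"))
}

# minimal trial table with fixed structure (subjects x conditions x trials)
toy_trial_table <- function(n_subj = 2L, n_per_cond = 4L, rt = 0.6,
                            seed = 3L) {
  set.seed(seed)
  g <- expand.grid(trial = seq_len(n_per_cond), condition = 1:6,
                   subject = sprintf("S%02d", seq_len(n_subj)))
  n <- nrow(g)
  data.frame(subject = g$subject, condition = g$condition,
             coherence = c(0.025, 0.05, 0.15, 0.25, 0.45, 0.7)[g$condition],
             direction = sample(c(-1L, 1L), n, TRUE),
             choice = sample(c(-1L, 1L), n, TRUE),
             rt_s = rep_len(rt, n), confidence = 2L,
             stringsAsFactors = FALSE)
}
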