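#' Filter trials by reaction time
#'
#' Removes trials with implausibly fast or slow responses. The default
#' bounds drop RTs faster than 250 ms or slower than 10 s; the bounds are
#' read as strict exclusions, so trials exactly at a bound are retained.
#'
#' @param trials A `TrialTable` data frame with an `rt_s` column.
#' @param min_rt,max_rt RT bounds in seconds (inclusive retention).
#' @return List with `trials` (the retained rows) and `report`, a data
#'   frame of retained/removed counts per subject and condition.
#' @export
filter_trials <- function(trials, min_rt = 0.25, max_rt = 10) {
  if (!nrow(trials)) stop("empty trial table")
  if (!(min_rt < max_rt)) stop("min_rt must be smaller than max_rt")
  keep <- trials$rt_s >= min_rt & trials$rt_s <= max_rt
  kept <- trials[keep, , drop = FALSE]
  tab <- table(subject = trials$subject, condition = trials$condition)
  tabk <- table(subject = kept$subject, condition = kept$condition)
  report <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(report)[3] <- "n_total"
  reportk <- as.data.frame(tabk, stringsAsFactors = FALSE)
  m <- match(paste(report$subject, report$condition),
             paste(reportk$subject, reportk$condition))
  report$n_retained <- ifelse(is.na(m), 0L, reportk$Freq[m])
  report$n_removed <- report$n_total - report$n_retained
  rownames(kept) <- NULL
  list(trials = kept, report = report)
}

#' Per-condition behavioral summaries
#'
#' Accuracy is the fraction of trials where the choice matched the motion
#' direction; RT summaries (mean RT and mean log RT) are computed over
#' correct trials only, and flagged missing for conditions without any
#' correct trial.
#'
#' @param trials A filtered `TrialTable`.
#' @return Data frame with one row per condition: `condition`, `n_trials`,
#'   `accuracy`, `mean_rt_correct`, `mean_log_rt_correct`, `rt_missing`.
#' @export
summarize_behavior <- function(trials) {
  if (!nrow(trials)) stop("empty trial table")
  conds <- sort(unique(trials$condition))
  out <- lapply(conds, function(cc) {
    d <- trials[trials$condition == cc, , drop = FALSE]
    ok <- d$choice == d$direction
    rts <- d$rt_s[ok]
    data.frame(condition = cc, n_trials = nrow(d),
               accuracy = mean(ok),
               mean_rt_correct = if (length(rts)) mean(rts) else NA_real_,
               mean_log_rt_correct = if (length(rts)) mean(log(rts)) else NA_real_,
               rt_missing = !length(rts))
  })
  do.call(rbind, out)
}

#' Standardize symptom scores and neural slopes
#'
#' Symptom scores are z-scored once across subjects (sample SD, n - 1
#' denominator). Neural slopes are z-scored across subjects separately
#' within each condition, matching how they enter the drift regression.
#'
#' @param scores Data frame with `subject`, `padua_raw`, `worry_raw` (or
#'   `padua`/`worry`).
#' @param slopes Optional named list of `subject x condition` slope matrices
#'   (one per band), or a single such matrix.
#' @return List with `scores` (input plus `padua_z`, `worry_z`) and
#'   `slopes_z` (same shape as `slopes`, standardized per condition).
#' @export
zscore_covariates <- function(scores, slopes = NULL) {
  if (nrow(scores) < 2) stop("need at least 2 subjects")
  pick <- function(a, b) if (!is.null(scores[[a]])) scores[[a]] else scores[[b]]
  padua <- pick("padua_raw", "padua")
  worry <- pick("worry_raw", "worry")
  zs <- function(x, label) {
    s <- sd(x)
    if (!is.finite(s) || s == 0)
      stop("covariate '", label, "' has zero variance")
    (x - mean(x)) / s
  }
  scores$padua_z <- zs(padua, "padua")
  scores$worry_z <- zs(worry, "worry")
  slopes_z <- NULL
  if (!is.null(slopes)) {
    zmat <- function(m, label) {
      out <- m
      for (cc in seq_len(ncol(m)))
        out[, cc] <- zs(m[, cc], paste0(label, " condition ", cc))
      out
    }
    slopes_z <- if (is.list(slopes)) {
      lapply(stats::setNames(names(slopes), names(slopes)),
             function(b) zmat(slopes[[b]], b))
    } else zmat(slopes, "slope")
  }
  list(scores = scores, slopes_z = slopes_z)
}
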