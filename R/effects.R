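#' Posterior summary of one parameter
#'
#' Median, central 95% credible interval and the posterior probability of a
#' positive sign. The `significant` flag follows the 95% reporting
#' convention (the credible interval excludes 0); it is a label, never a
#' branch in any computation.
#'
#' @param draws A `posterior_draws` object, or a numeric vector of draws.
#' @param parameter Parameter name (ignored for numeric input).
#' @param level Credible level (default 0.95).
#' @return One-row data frame: `parameter`, `median`, `ci_low`, `ci_high`,
#'   `p_positive`, `significant`.
#' @export
summarize_effect <- function(draws, parameter = NULL, level = 0.95) {
  x <- if (is.numeric(draws)) draws else {
    m <- draws_matrix(draws)
    if (is.null(parameter) || !parameter %in% colnames(m))
      stop("parameter '", parameter, "' not found in draws")
    m[, parameter]
  }
  a <- (1 - level) / 2
  qs <- unname(quantile(x, c(a, 1 - a), type = 7))
  data.frame(parameter = if (is.null(parameter)) "draws" else parameter,
             median = median(x), ci_low = qs[1], ci_high = qs[2],
             p_positive = mean(x > 0),
             significant = qs[1] > 0 | qs[2] < 0,
             stringsAsFactors = FALSE)
}

#' Draw-wise contrast between two parameters
#'
#' Summarizes the distribution of `a - b` over paired draws, e.g. an
#' easy-minus-hard condition contrast within a coefficient block, or an
#' OCD-versus-worry contrast within a condition.
#'
#' @param draws A `posterior_draws` object (both parameters must be in it),
#'   or a list of two `posterior_draws` sharing draw counts.
#' @param a,b Parameter names.
#' @param level Credible level.
#' @return One-row effect summary for the difference (named `a - b`).
#' @export
condition_contrast <- function(draws, a, b, level = 0.95) {
  grab <- function(d, p) {
    m <- draws_matrix(d)
    if (!p %in% colnames(m)) stop("parameter '", p, "' not found")
    m[, p]
  }
  if (inherits(draws, "posterior_draws")) {
    xa <- grab(draws, a)
    xb <- grab(draws, b)
  } else {
    xa <- grab(draws[[1]], a)
    xb <- grab(draws[[2]], b)
  }
  if (length(xa) != length(xb)) stop("mismatched draw counts")
  out <- summarize_effect(xa - xb)
  out$parameter <- paste(a, "-", b)
  out
}

#' Coefficient change between full and reduced fits (mediation test)
#'
#' The candidate-mediator logic: if neural slopes mediate the symptom
#' effect on drift, adding them to the regression should attenuate the
#' symptom coefficient. The two models are fitted independently, so the
#' change distribution is formed by pairing draws by index after a random
#' permutation (valid for independent posteriors) and summarizing
#' full - reduced.
#'
#' @param full_draws,reduced_draws `posterior_draws` from the full and
#'   reduced fits.
#' @param parameter Parameter name present in both fits.
#' @param seed Seed for the pairing permutation.
#' @param level Credible level.
#' @return One-row effect summary of the change.
#' @export
mediation_change <- function(full_draws, reduced_draws, parameter,
                             seed = 1L, level = 0.95) {
  mf <- draws_matrix(full_draws)
  mr <- draws_matrix(reduced_draws)
  for (m in list(mf, mr))
    if (!parameter %in% colnames(m))
      stop("parameter '", parameter, "' missing from one of the fits")
  xf <- mf[, parameter]
  xr <- mr[, parameter]
  n <- min(length(xf), length(xr))
  set.seed(seed)
  xf <- xf[sample(length(xf), n)]
  xr <- xr[sample(length(xr), n)]
  out <- summarize_effect(xf - xr, level = level)
  out$parameter <- paste0("change:", parameter)
  out
}

#' Summarize a whole coefficient block across conditions
#'
#' @param draws A `posterior_draws` object.
#' @param stem Coefficient stem, e.g. `"drift_padua"`; summarizes
#'   `stem_c1` ... `stem_c6`.
#' @param level Credible level.
#' @return Six-row data frame of effect summaries with a `condition`
#'   column.
#' @export
summarize_block <- function(draws, stem, level = 0.95) {
  out <- do.call(rbind, lapply(1:6, function(cc)
    summarize_effect(draws, paste0(stem, "_c", cc), level = level)))
  out$condition <- 1:6
  out
}
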