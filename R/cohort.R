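#' Generate a synthetic cohort with binned OCD-symptom coverage
#'
#' Emulates a pre-screening design that fills four Padua Inventory score
#' bins (0-16, 17-33, 34-50, 51+) with requested counts. Worry (PSWQ-like)
#' scores are drawn through a Gaussian copula so they correlate positively
#' with the Padua score and are right-skewed towards the upper range.
#' Per-subject drift and boundary deviations are drawn from the truth's
#' group distributions and recorded so recovery tests never re-derive them.
#'
#' @param n_subjects Total cohort size; must equal `sum(bin_targets)`.
#' @param bin_targets Length-4 counts per Padua bin. Default matches a
#'   67-participant design with 19/18/15/15 per bin.
#' @param truth A [ground_truth()] object supplying the subject-effect SDs.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param worry_cor Copula correlation between Padua and worry scores.
#' @param worry_shape Beta-distribution shapes for the worry marginal on the
#'   16-80 PSWQ range; the default `c(3, 1.7)` skews mass to the upper end.
#' @return A data frame of subject profiles: `subject_id`, `padua`, `worry`,
#'   `true_drift_offset`, `true_boundary_offset`, `true_ndt`.
#' @export
generate_cohort <- function(n_subjects = 67L,
                            bin_targets = c(19L, 18L, 15L, 15L),
                            truth = ground_truth(), seed = 1L,
                            worry_cor = 0.45, worry_shape = c(3, 1.7)) {
  if (length(bin_targets) != 4L)
    stop("bin_targets must have length 4")
  if (sum(bin_targets) != n_subjects)
    stop("n_subjects (", n_subjects, ") must equal sum(bin_targets) (",
         sum(bin_targets), ")")
  set.seed(seed)
  lo <- c(0L, 17L, 34L, 51L)
  hi <- c(16L, 33L, 50L, 80L)
  padua <- unlist(lapply(1:4, function(b) {
    if (bin_targets[b] == 0L) return(integer(0))
    sample(lo[b]:hi[b], bin_targets[b], replace = TRUE)
  }))
  n <- length(padua)
  # copula: worry quantile tied to the padua quantile plus independent noise
  zp <- qnorm((rank(padua, ties.method = "random") - 0.5) / n)
  zw <- worry_cor * zp + sqrt(1 - worry_cor^2) * rnorm(n)
  worry <- round(16 + 64 * qbeta(pnorm(zw), worry_shape[1], worry_shape[2]))
  ndt <- pmax(0.05, rnorm(n, truth$ndt_mean, truth$ndt_sd))
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    padua = as.integer(padua),
    worry = as.integer(worry),
    true_drift_offset = rnorm(n, 0, truth$sigma_drift),
    true_boundary_offset = rnorm(n, 0, truth$sigma_boundary),
    true_ndt = ndt,
    stringsAsFactors = FALSE)
}

#' @importFrom stats qbeta rank
NULL
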