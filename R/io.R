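#' Read and write trial tables, layouts, slopes and draws as plain text
#'
#' Trial tables, channel layouts and slope tables round-trip through CSV;
#' posterior draws serialize to a tidy long table (chain, iter, parameter,
#' value) with a small header-free diagnostics CSV alongside.
#'
#' @param trials,path,layout,slopes,draws Objects and file paths.
#' @name driftband-io
NULL

#' @rdname driftband-io
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials[, c("subject", "condition", "coherence",
                              "direction", "choice", "rt_s", "confidence")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname driftband-io
#' @export
read_trial_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "condition", "coherence", "direction", "choice",
            "rt_s", "confidence")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(out$rt_s <= 0)) stop("rt_s must be positive")
  out
}

#' @rdname driftband-io
#' @export
write_layout <- function(layout, path) {
  utils::write.csv(layout[, c("name", "is_frontal")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname driftband-io
#' @param band Band label stored in the slope table.
#' @export
write_slopes <- function(slopes, band, path) {
  df <- data.frame(subject = rep(rownames(slopes), ncol(slopes)),
                   condition = rep(seq_len(ncol(slopes)),
                                   each = nrow(slopes)),
                   band = band, slope = as.numeric(slopes))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname driftband-io
#' @export
write_draws <- function(draws, path) {
  arr <- draws$draws
  d <- dim(arr)
  df <- data.frame(
    chain = rep(seq_len(d[1]), times = d[2] * d[3]),
    iter = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    parameter = rep(dimnames(arr)[[3]], each = d[1] * d[2]),
    value = as.numeric(arr))
  utils::write.csv(df, path, row.names = FALSE)
  diag_path <- sub("\\.csv$", "_diagnostics.csv", path)
  utils::write.csv(draws$diagnostics, diag_path, row.names = FALSE)
  invisible(path)
}

#' @rdname driftband-io
#' @export
read_draws <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  params <- unique(df$parameter)
  chains <- sort(unique(df$chain))
  iters <- sort(unique(df$iter))
  arr <- array(NA_real_, c(length(chains), length(iters), length(params)),
               dimnames = list(NULL, NULL, params))
  for (p in seq_along(params)) {
    sub <- df[df$parameter == params[p], ]
    arr[cbind(sub$chain, sub$iter, p)] <- sub$value
  }
  arr
}
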