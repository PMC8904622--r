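#' Time-frequency analysis specification
#'
#' Frequencies of interest are 32-100 Hz in 4 Hz steps for gamma and
#' 12-28 Hz in 4 Hz steps for beta, estimated with a 250 ms sliding window
#' and +/-8 Hz multitaper smoothing, normalized against the 200 ms
#' pre-stimulus baseline.
#'
#' @param band `"gamma"` or `"beta"`.
#' @param window_ms Taper window length (ms).
#' @param smoothing_hz Half-bandwidth of spectral smoothing (Hz); must
#'   exceed the window's Rayleigh resolution.
#' @param baseline_ms Baseline window `c(start, end)` in ms.
#' @param step_ms Output time-grid step (ms).
#' @return List of class `tf_spec` including the frequency grid and taper
#'   count (2 * window * smoothing - 1 DPSS tapers).
#' @export
tf_spec <- function(band = c("gamma", "beta"), window_ms = 250,
                    smoothing_hz = 8, baseline_ms = c(-200, 0),
                    step_ms = 50) {
  band <- match.arg(band)
  freqs <- if (band == "gamma") seq(32, 100, by = 4) else seq(12, 28, by = 4)
  rayleigh <- 1000 / window_ms
  if (smoothing_hz <= rayleigh)
    stop("smoothing (", smoothing_hz, " Hz) must exceed the Rayleigh ",
         "resolution of the window (", rayleigh, " Hz)")
  nw <- (window_ms / 1000) * smoothing_hz  # time-half-bandwidth product
  structure(list(band = band, freqs = freqs, window_ms = window_ms,
                 smoothing_hz = smoothing_hz, baseline_ms = baseline_ms,
                 step_ms = step_ms, nw = nw,
                 n_tapers = max(1L, floor(2 * nw) - 1L)),
            class = "tf_spec")
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as eigenvectors of the standard symmetric tridiagonal matrix
#' whose eigenvectors coincide with the DPSS (Slepian 1978; Percival &
#' Walden 1993, ch. 8), ordered by decreasing spectral concentration and
#' normalized to unit energy.
#'
#' @param n Window length in samples.
#' @param nw Time-half-bandwidth product.
#' @param k Number of tapers.
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, k >= 1, k <= n)
  w <- nw / n
  i <- seq_len(n) - 1
  dg <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- i[-1] * (n - i[-1]) / 2
  A <- matrix(0, n, n)
  diag(A) <- dg
  A[cbind(seq_len(n - 1), 2:n)] <- off
  A[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    # sign convention: positive mean (even tapers) / positive initial slope
    s <- if (sum(tap[, j]) != 0) sign(sum(tap[, j])) else
      sign(tap[2, j] - tap[1, j])
    if (s < 0) tap[, j] <- -tap[, j]
  }
  tap
}

#' Multitaper spectrogram of epoched signals
#'
#' DPSS-tapered sliding-window Fourier power at the spec's frequencies of
#' interest. Window centers step along `spec$step_ms`; windows that would
#' extend past the epoch edges are dropped rather than zero-padded. Power
#' at each time/frequency is the average over tapers of the squared
#' magnitude of the tapered Fourier coefficient.
#'
#' @param epochs Array `[channel, time, trial]`.
#' @param times_ms Time axis of the epoch (ms).
#' @param spec A [tf_spec()].
#' @param sampling_rate Hz; must be at least twice the highest frequency of
#'   interest.
#' @return Array `[trial, channel, frequency, time]` of non-negative power
#'   with a `time_ms` attribute giving the window centers.
#' @export
multitaper_power <- function(epochs, times_ms, spec, sampling_rate) {
  stopifnot(length(dim(epochs)) == 3, dim(epochs)[2] == length(times_ms))
  if (sampling_rate < 2 * max(spec$freqs))
    stop("sampling_rate below Nyquist for the requested frequencies")
  nwin <- round(spec$window_ms / 1000 * sampling_rate)
  if (nwin > length(times_ms)) stop("window longer than the epoch")
  half <- (nwin - 1) / 2
  tap <- dpss_tapers(nwin, spec$nw, spec$n_tapers)
  fft_freqs <- (seq_len(nwin) - 1) * sampling_rate / nwin
  fbin <- vapply(spec$freqs, function(f) which.min(abs(fft_freqs - f)),
                 integer(1))
  if (max(abs(fft_freqs[fbin] - spec$freqs)) > sampling_rate / nwin / 2 +
      1e-9)
    stop("frequency grid of the window cannot resolve the requested freqs")
  centers <- seq(ceiling(times_ms[1] / spec$step_ms) * spec$step_ms,
                 times_ms[length(times_ms)], by = spec$step_ms)
  cidx <- vapply(centers, function(tc) which.min(abs(times_ms - tc)),
                 integer(1))
  ok <- cidx - ceiling(half) >= 1 &
    cidx + ceiling(half) <= length(times_ms) &
    abs(times_ms[cidx] - centers) < spec$step_ms / 2
  centers <- centers[ok]
  cidx <- cidx[ok]
  Ch <- dim(epochs)[1]; Tr <- dim(epochs)[3]
  out <- array(0, dim = c(Tr, Ch, length(spec$freqs), length(centers)))
  offs <- seq_len(nwin) - 1 - floor(half)
  for (ti in seq_along(cidx)) {
    sl <- cidx[ti] + offs
    for (tr in seq_len(Tr)) {
      seg <- t(matrix(epochs[, sl, tr], nrow = Ch))  # nwin x Ch
      ptot <- matrix(0, length(fbin), Ch)
      for (k in seq_len(spec$n_tapers)) {
        X <- stats::mvfft(seg * tap[, k])
        ptot <- ptot + abs(X[fbin, , drop = FALSE])^2
      }
      out[tr, , , ti] <- t(ptot) / spec$n_tapers
    }
  }
  attr(out, "time_ms") <- centers
  attr(out, "freqs") <- spec$freqs
  out
}

#' Log-transform and baseline z-normalization of power
#'
#' Per subject, condition, channel and frequency: power is log-transformed,
#' then centered and scaled by the mean and SD of log power over the
#' pre-stimulus baseline, pooling that stratum's trials and baseline time
#' points. Multiplicative gains per channel therefore cancel exactly.
#'
#' @param power Array `[trial, channel, frequency, time]` with a `time_ms`
#'   attribute (e.g. from [multitaper_power()]).
#' @param strata Per-trial stratum labels (subject x condition); trials in
#'   the same stratum share baseline statistics.
#' @param baseline_ms Baseline window `c(start, end)` in ms.
#' @return Normalized array of the same shape.
#' @export
log_baseline_normalize <- function(power, strata,
                                   baseline_ms = c(-200, 0)) {
  times <- attr(power, "time_ms")
  if (is.null(times)) stop("power must carry a time_ms attribute")
  bidx <- which(times >= baseline_ms[1] & times <= baseline_ms[2])
  if (!length(bidx)) stop("no time points fall in the baseline window")
  stopifnot(dim(power)[1] == length(strata))
  lp <- log(power)
  out <- lp
  for (st in unique(strata)) {
    tr <- which(strata == st)
    for (ch in seq_len(dim(power)[2])) {
      for (fr in seq_len(dim(power)[3])) {
        base <- lp[tr, ch, fr, bidx]
        mu <- mean(base)
        s <- sd(as.numeric(base))
        if (!is.finite(s) || s == 0)
          stop("zero baseline SD in stratum '", st, "', channel ", ch,
               ", frequency index ", fr)
        out[tr, ch, fr, ] <- (lp[tr, ch, fr, ] - mu) / s
      }
    }
  }
  attributes(out) <- attributes(power)
  out
}

#' Average normalized power across a band's frequencies
#'
#' @param npower Normalized array `[trial, channel, frequency, time]`.
#' @param freqs Frequencies that must all be present (defaults to the
#'   array's own frequency axis).
#' @return Array `[trial, channel, time]` with the `time_ms` attribute kept.
#' @export
band_average <- function(npower, freqs = attr(npower, "freqs")) {
  have <- attr(npower, "freqs")
  if (!is.null(have) && !is.null(freqs)) {
    if (!all(freqs %in% have))
      stop("missing frequencies: ",
           paste(setdiff(freqs, have), collapse = ", "))
    sel <- match(freqs, have)
  } else sel <- seq_len(dim(npower)[3])
  out <- apply(npower[, , sel, , drop = FALSE], c(1, 2, 4), mean)
  attr(out, "time_ms") <- attr(npower, "time_ms")
  out
}
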