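# DPSS tapers, multitaper spectrogram, baseline normalization, band average.

test_that("DPSS tapers are orthonormal and spectrally concentrated", {
  tap <- dpss_tapers(125, 2, 3)
  expect_equal(crossprod(tap), diag(3), tolerance = 1e-8)
  # leading taper concentrates energy inside +/- W = nw/n cycles/sample
  n <- 125
  pad <- 4096
  X <- abs(fft(c(tap[, 1], rep(0, pad - n))))^2
  f <- (seq_len(pad) - 1) / pad
  inband <- f <= 2 / n | f >= 1 - 2 / n
  expect_gt(sum(X[inband]) / sum(X), 0.99)
})

test_that("tf_spec encodes the band definitions and taper count", {
  g <- tf_spec("gamma")
  b <- tf_spec("beta")
  expect_equal(g$freqs, seq(32, 100, 4))
  expect_equal(b$freqs, seq(12, 28, 4))
  expect_equal(g$n_tapers, 3L)   # 2 * (0.25 s * 8 Hz) - 1
  expect_error(tf_spec("gamma", smoothing_hz = 2), "Rayleigh")
})

test_that("a pure 40 Hz tone peaks in the 40 Hz bin", {
  fs <- 500
  times <- seq(-450, 1050, by = 1000 / fs)
  sig <- array(sin(2 * pi * 40 * times / 1000), dim = c(1, length(times), 2))
  p <- multitaper_power(sig, times, tf_spec("gamma"), fs)
  freqs <- attr(p, "freqs")
  avg <- apply(p[1, 1, , ], 1, mean)
  expect_equal(freqs[which.max(avg)], 40)
})

test_that("zero signal gives zero power; white noise is flat", {
  fs <- 500
  times <- seq(-450, 1050, by = 1000 / fs)
  z <- array(0, dim = c(1, length(times), 1))
  expect_equal(max(multitaper_power(z, times, tf_spec("beta"), fs)), 0)
  set.seed(31)
  wn <- array(rnorm(length(times) * 40), dim = c(1, length(times), 40))
  p <- multitaper_power(wn, times, tf_spec("gamma"), fs)
  byfreq <- apply(p, 3, mean)
  expect_lt((max(byfreq) - min(byfreq)) / mean(byfreq), 0.25)
})

test_that("window-epoch geometry is enforced", {
  fs <- 500
  short <- seq(0, 100, by = 2)
  expect_error(multitaper_power(array(0, c(1, length(short), 1)), short,
                                tf_spec("beta"), fs), "window longer")
  expect_error(multitaper_power(array(0, c(1, 800, 1)), seq_len(800),
                                tf_spec("gamma"), 150), "Nyquist")
})

test_that("baseline normalization matches the hand formula exactly", {
  # constructed log-power with known baseline mean and SD
  times <- seq(-200, 800, by = 50)
  n_base <- sum(times <= 0)
  set.seed(32)
  pow <- array(exp(rnorm(2 * 1 * 1 * length(times))),
               dim = c(2, 1, 1, length(times)))
  attr(pow, "time_ms") <- times
  z <- log_baseline_normalize(pow, strata = c("a", "a"))
  lp <- log(pow)
  base <- lp[, 1, 1, seq_len(n_base)]
  expect_equal(as.numeric(z[1, 1, 1, ]),
               (lp[1, 1, 1, ] - mean(base)) / sd(as.numeric(base)))
  # normalized baseline has mean 0 within the stratum
  expect_equal(mean(z[, 1, 1, seq_len(n_base)]), 0, tolerance = 1e-12)
})

test_that("normalization is invariant to multiplicative gain", {
  times <- seq(-200, 800, by = 50)
  set.seed(33)
  pow <- array(exp(rnorm(3 * 2 * 2 * length(times))),
               dim = c(3, 2, 2, length(times)))
  attr(pow, "time_ms") <- times
  z1 <- log_baseline_normalize(pow, strata = rep("a", 3))
  pow2 <- pow * 37.5
  attr(pow2, "time_ms") <- times
  z2 <- log_baseline_normalize(pow2, strata = rep("a", 3))
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("zero baseline SD is rejected with the stratum named", {
  times <- seq(-200, 400, by = 50)
  pow <- array(1, dim = c(2, 1, 1, length(times)))
  attr(pow, "time_ms") <- times
  expect_error(log_baseline_normalize(pow, strata = c("s1", "s1")), "s1")
})

test_that("band averaging is an unweighted mean over frequencies", {
  set.seed(34)
  arr <- array(rnorm(2 * 3 * 4 * 5), dim = c(2, 3, 4, 5))
  attr(arr, "freqs") <- c(12, 16, 20, 24)
  attr(arr, "time_ms") <- 1:5
  avg <- band_average(arr)
  expect_equal(avg[1, 2, 3], mean(arr[1, 2, , 3]))
  expect_equal(avg[2, 1, 5], mean(arr[2, 1, , 5]))
  # +1/-1 over two freqs cancels
  two <- array(rep(c(1, -1), each = 1), dim = c(1, 1, 2, 1))
  attr(two, "freqs") <- c(12, 16)
  expect_equal(as.numeric(band_average(two)), 0)
  expect_error(band_average(arr, freqs = c(12, 40)), "missing")
})

test_that("steeper planted envelopes give steeper band-power ramps", {
  fs <- 500
  # broadband noise keeps the baseline-z denominator comparable across
  # channels (a noiseless sinusoid has a degenerate baseline SD)
  slopes <- c(a = 0, b = 0.5, c = 1, d = 2)
  raw <- generate_raw_oscillations(10, slopes, band = c(50, 70),
                                   noise_sd = 0.5, seed = 41)
  p <- multitaper_power(raw$signal, raw$times_ms, tf_spec("gamma"), fs)
  z <- log_baseline_normalize(p, strata = rep("a", 10))
  bp <- band_average(z)
  tm <- attr(bp, "time_ms")
  i0 <- which.min(abs(tm - 300))
  i1 <- which.min(abs(tm - 800))
  est <- vapply(seq_along(slopes),
                function(ch) mean(bp[, ch, i1] - bp[, ch, i0]), numeric(1))
  expect_equal(order(est), seq_along(slopes))
  expect_lt(abs(est[1]), 1)   # flat envelope: near-zero ramp in z units
})
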