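# Electrode weighting plumbing, aggregation, slope statistic, projection.

test_that("difficulty labels map the six conditions correctly", {
  tr <- toy_trial_table(1, 1)
  lab <- difficulty_labels(tr)
  expect_equal(lab[tr$condition %in% 1:2], c(0L, 0L))
  expect_equal(lab[tr$condition %in% 5:6], c(1L, 1L))
  expect_true(all(is.na(lab[tr$condition %in% 3:4])))
})

test_that("median hard RT uses the median and snaps to the grid", {
  grid <- seq(-200, 1000, by = 50)
  tr <- toy_trial_table(1, 3)
  hard <- tr$condition %in% 1:2
  tr$rt_s[hard] <- rep(c(0.6, 0.8, 1.0), length.out = sum(hard))
  expect_equal(unname(median_hard_rt(tr, grid)), 800)
  # even count: midpoint convention
  tr2 <- tr[tr$condition == 1, ][1:2, ]
  tr2$rt_s <- c(0.6, 1.0)
  expect_equal(unname(median_hard_rt(tr2, grid)), 800)
  # snapping 0.83 s on a 50 ms grid -> 850
  tr3 <- tr2[1, , drop = FALSE]
  tr3$rt_s <- 0.83
  expect_equal(unname(median_hard_rt(tr3, grid)), 850)
  expect_error(median_hard_rt(tr[tr$condition > 2, ], grid), "no hard")
})

test_that("apply_weights matches a brute-force nested-loop oracle", {
  set.seed(51)
  tr <- toy_trial_table(2, 3)
  channels <- paste0("ch", 1:5)
  pw <- planted_power_tensor(2, 18, channels, NA, 0, tr, seed = 52)
  W <- matrix(rnorm(4 * 5), 4, 5,
              dimnames = list(NULL, paste0("w[", channels, "]")))
  agg <- apply_weights(W, pw, tr)
  # brute force: for each draw/subject/condition/time, sum over channels of
  # weight x trial-mean power
  times <- attr(pw, "time_ms")
  trial_rows <- attr(pw, "trial_rows")
  for (d in c(1, 4)) for (s in 1:2) for (cc in c(1, 6)) {
    j <- which(tr$condition[trial_rows[s, ]] == cc)
    for (ti in c(1, 10)) {
      ref <- 0
      for (ch in 1:5)
        ref <- ref + W[d, ch] * mean(pw[s, j, ch, ti])
      expect_equal(unname(agg[d, s, cc, ti]), unname(ref), tolerance = 1e-10)
    }
  }
})

test_that("aggregation is linear with the expected degenerate cases", {
  tr <- toy_trial_table(2, 3)
  channels <- paste0("ch", 1:4)
  pw <- planted_power_tensor(2, 18, channels, NA, 0, tr, seed = 53)
  W0 <- matrix(0, 2, 4, dimnames = list(NULL, paste0("w[", channels, "]")))
  expect_true(all(apply_weights(W0, pw, tr) == 0))
  # single nonzero coefficient picks out one channel's mean power
  W1 <- W0; W1[, 2] <- 3
  agg <- apply_weights(W1, pw, tr)
  j <- which(tr$condition[attr(pw, "trial_rows")[1, ]] == 2)
  expect_equal(unname(agg[1, 1, 2, 7]), 3 * mean(pw[1, j, 2, 7]),
               tolerance = 1e-10)
  # linearity in the power tensor
  pw2 <- pw; pw2[] <- 2 * pw[]
  for (a in setdiff(names(attributes(pw)), c("dim", "dimnames")))
    attr(pw2, a) <- attr(pw, a)
  Wr <- matrix(rnorm(8), 2, 4,
               dimnames = list(NULL, paste0("w[", channels, "]")))
  expect_equal(2 * apply_weights(Wr, pw, tr),
               apply_weights(Wr, pw2, tr), tolerance = 1e-10)
  # channel mismatch errors
  Wbad <- matrix(0, 2, 4,
                 dimnames = list(NULL, paste0("w[x", 1:4, "]")))
  expect_error(apply_weights(Wbad, pw, tr), "mismatch")
})

test_that("slope statistic telescopes exactly", {
  times <- seq(-200, 1000, by = 50)
  # linear aggregate y(t) = 2 + 0.004 t gives increments of 0.2
  y <- 2 + 0.004 * times
  agg <- array(rep(y, each = 4), dim = c(2, 2, 1, length(times)))
  agg <- aperm(array(y, dim = c(length(times), 2, 2, 1)), c(2, 3, 4, 1))
  attr(agg, "time_ms") <- times
  sl <- slope_statistic(agg)
  expect_equal(as.numeric(sl$draws), rep(0.2, 4), tolerance = 1e-12)
  # arbitrary series: equals (y(800) - y(300)) / 10
  set.seed(54)
  arr <- array(rnorm(3 * 2 * 6 * length(times)),
               dim = c(3, 2, 6, length(times)))
  attr(arr, "time_ms") <- times
  sl2 <- slope_statistic(arr)
  i0 <- which(times == 300); i1 <- which(times == 800)
  expect_equal(sl2$draws, (arr[, , , i1] - arr[, , , i0]) / 10,
               tolerance = 1e-12)
  # missing grid points error
  attr(arr, "time_ms") <- times + 5
  expect_error(slope_statistic(arr), "missing")
})

test_that("slope estimator is unbiased on noisy ramps", {
  times <- seq(-200, 1000, by = 50)
  true_slope <- 0.2
  set.seed(55)
  reps <- 1000
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    y <- true_slope * (times / 50) + rnorm(length(times), 0, 0.5)
    arr <- array(y, dim = c(1, 1, 1, length(times)))
    attr(arr, "time_ms") <- times
    est[r] <- slope_statistic(arr)$draws[1]
  }
  expect_lt(abs(mean(est) - true_slope), 3 * sd(est) / sqrt(reps))
})

test_that("scalp projection is 1 for the aggregate itself, 0 if orthogonal", {
  times <- seq(-200, 1000, by = 50)
  nt <- length(times)
  # build a tensor whose channel 1 equals the (single-draw) aggregate
  y <- sin(seq(0, 3 * pi, length.out = nt))
  orth <- cos(seq(0, 3 * pi, length.out = nt))
  orth <- orth - sum(orth * y) / sum(y * y) * y   # exactly orthogonal
  tr <- toy_trial_table(1, 1)
  pow <- array(0, dim = c(1, 6, 2, nt),
               dimnames = list("S01", NULL, c("same", "orth"), NULL))
  for (j in 1:6) {
    pow[1, j, 1, ] <- y
    pow[1, j, 2, ] <- orth
  }
  pw <- structure(pow, band = "gamma", time_ms = times,
                  baseline_ms = c(-200, 0),
                  trial_rows = matrix(1:6, 1, 6),
                  retained = matrix(TRUE, 1, 6),
                  class = c("band_power_tensor", "array"))
  agg <- array(0, dim = c(1, 1, 6, nt))
  for (cc in 1:6) agg[1, 1, cc, ] <- y
  attr(agg, "time_ms") <- times
  pr <- scalp_projection(pw, agg, tr)
  expect_equal(unname(pr["same"]), 1, tolerance = 1e-10)
  expect_equal(unname(pr["orth"]), 0, tolerance = 1e-10)
})

test_that("projection equals regression through the origin (oracle)", {
  times <- seq(-200, 1000, by = 50)
  nt <- length(times)
  set.seed(56)
  tr <- toy_trial_table(1, 1)
  pow <- array(rnorm(6 * 3 * nt), dim = c(1, 6, 3, nt),
               dimnames = list("S01", NULL, paste0("ch", 1:3), NULL))
  pw <- structure(pow, band = "gamma", time_ms = times,
                  baseline_ms = c(-200, 0),
                  trial_rows = matrix(1:6, 1, 6),
                  retained = matrix(TRUE, 1, 6),
                  class = c("band_power_tensor", "array"))
  yv <- rnorm(nt)
  agg <- array(rep(yv, each = 6), dim = c(1, 1, 6, nt))
  for (cc in 1:6) agg[1, 1, cc, ] <- yv
  attr(agg, "time_ms") <- times
  pr <- scalp_projection(pw, agg, tr)
  X <- apply(pow[1, , , ], c(2, 3), mean)   # ch x time
  for (ch in 1:3) {
    beta <- sum(X[ch, ] * yv) / sum(yv^2)   # least squares through origin
    expect_equal(unname(pr[ch]), beta, tolerance = 1e-10)
  }
})

test_that("frontal exclusion removes exactly the 16 flagged channels", {
  lay <- channel_layout()
  expect_equal(nrow(lay), 64L)
  expect_equal(sum(lay$is_frontal), 16L)
  red <- exclude_frontal(lay)
  expect_equal(nrow(red), 48L)
  expect_false(any(red$is_frontal))
  # tensor path
  gt <- ground_truth()
  co <- tiny_cohort(2, gt, seed = 57)
  sl <- generate_neural_slopes(co, gt, seed = 58)
  tr <- tiny_trials(co, gt, n_per_cond = 2, seed = 59, slopes = sl)
  pw <- generate_power(co, tr, truth = gt, slopes = sl, band = "gamma",
                       seed = 60)
  red_t <- exclude_frontal(pw)
  expect_equal(dim(red_t)[3], 48L)
  expect_identical(attr(red_t, "trial_rows"), attr(pw, "trial_rows"))
  # layout with no frontal flags set is an identity
  lay2 <- lay; lay2$is_frontal <- FALSE
  expect_equal(nrow(exclude_frontal(lay2)), 64L)
})
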