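# Cohort, behavior, band-power and raw-oscillation generators.

test_that("cohort fills the requested symptom bins exactly", {
  co <- generate_cohort(67, c(19L, 18L, 15L, 15L), seed = 1)
  expect_equal(nrow(co), 67L)
  expect_equal(sum(co$padua <= 16), 19L)
  expect_equal(sum(co$padua >= 17 & co$padua <= 33), 18L)
  expect_equal(sum(co$padua >= 34 & co$padua <= 50), 15L)
  expect_equal(sum(co$padua >= 51), 15L)
  # single-bin case
  one <- generate_cohort(1, c(1L, 0L, 0L, 0L), seed = 2)
  expect_true(one$padua >= 0 && one$padua <= 16)
  # mismatched totals error
  expect_error(generate_cohort(10, c(1L, 1L, 1L, 1L)), "must equal")
})

test_that("cohorts are deterministic under a fixed seed", {
  expect_identical(generate_cohort(20, c(5L, 5L, 5L, 5L), seed = 7),
                   generate_cohort(20, c(5L, 5L, 5L, 5L), seed = 7))
})

test_that("worry scores correlate with padua and skew to the upper range", {
  cors <- skews <- numeric(20)
  for (r in 1:20) {
    co <- generate_cohort(40, c(10L, 10L, 10L, 10L), seed = 100 + r)
    cors[r] <- cor(co$padua, co$worry)
    skews[r] <- mean((co$worry - mean(co$worry))^3) / sd(co$worry)^3
  }
  expect_gt(mean(cors), 0.2)
  expect_lt(mean(skews), 0)  # mass towards the upper range: left tail
})

test_that("behavior generation has the contracted shape and determinism", {
  gt <- truth_behavior_only()
  co <- tiny_cohort(4, gt, seed = 3)
  tr <- generate_behavior(co, gt, n_trials_per_condition = 120, seed = 4)
  expect_equal(nrow(tr), 4 * 720)
  expect_equal(unname(table(tr$subject)[1]), 720L)
  expect_true(all(tr$direction %in% c(-1L, 1L)))
  expect_true(all(tr$rt_s > 0))
  expect_identical(tr, generate_behavior(co, gt,
                                         n_trials_per_condition = 120,
                                         seed = 4))
})

test_that("very large drift in the easiest condition drives accuracy to 1", {
  gt <- truth_behavior_only(drift_c = c(0.5, 1, 2, 3, 4, 40))
  co <- tiny_cohort(4, gt, seed = 5)
  tr <- tiny_trials(co, gt, n_per_cond = 30, seed = 6)
  s <- summarize_behavior(tr)
  expect_gt(s$accuracy[6], 0.99)
})

test_that("negative easy-condition OCD coefficients depress easy accuracy", {
  gt <- truth_behavior_only(drift_padua = c(0, 0, 0, 0, -0.3, -0.3))
  cors <- numeric(20)
  for (r in 1:20) {
    co <- generate_cohort(40, c(10L, 10L, 10L, 10L), gt, seed = 300 + r)
    tr <- generate_behavior(co, gt, n_trials_per_condition = 12,
                            seed = 400 + r)
    easy <- tr[tr$condition >= 5, ]
    acc <- tapply(easy$choice == easy$direction, easy$subject, mean)
    cors[r] <- cor(co$padua[match(names(acc), co$subject_id)], acc)
  }
  expect_lt(mean(cors), -0.1)
  expect_gt(mean(cors < 0), 0.8)
})

test_that("generated neural slopes track the planted regression", {
  gt <- ground_truth()   # beta b_padua = -0.3, gamma 0
  cors_b <- cors_g <- numeric(20)
  for (r in 1:20) {
    co <- generate_cohort(40, c(10L, 10L, 10L, 10L), gt, seed = 500 + r)
    sl <- generate_neural_slopes(co, gt, seed = 600 + r)
    cors_b[r] <- cor(co$padua, rowMeans(sl[, , "beta"]))
    cors_g[r] <- cor(co$padua, rowMeans(sl[, , "gamma"]))
  }
  expect_lt(mean(cors_b), -0.2)
  expect_lt(abs(mean(cors_g)), 0.15)
})

test_that("power tensors are deterministic with zero ramp in the baseline", {
  gt <- ground_truth()
  co <- tiny_cohort(3, gt, seed = 8)
  sl <- generate_neural_slopes(co, gt, seed = 9)
  tr <- tiny_trials(co, gt, n_per_cond = 4, seed = 10, slopes = sl)
  p1 <- generate_power(co, tr, truth = gt, slopes = sl, band = "beta",
                       seed = 11)
  p2 <- generate_power(co, tr, truth = gt, slopes = sl, band = "beta",
                       seed = 11)
  expect_identical(p1, p2)
  # baseline means are noise-only: grand mean near 0, no systematic ramp
  times <- attr(p1, "time_ms")
  base <- p1[, , , times <= 0]
  expect_lt(abs(mean(base)), 0.05)
  # time-grid contract
  expect_error(generate_power(co, tr, truth = gt, slopes = sl,
                              time_grid_ms = seq(0, 800, 50), seed = 1),
               "baseline")
})

test_that("planted beta ramps are negative at parieto-occipital channels", {
  gt <- ground_truth()
  co <- tiny_cohort(4, gt, seed = 12)
  sl <- generate_neural_slopes(co, gt, seed = 13)
  tr <- tiny_trials(co, gt, n_per_cond = 12, seed = 14, slopes = sl)
  p <- generate_power(co, tr, truth = gt, slopes = sl, band = "beta",
                      seed = 15)
  times <- attr(p, "time_ms")
  late <- times >= 600
  poz <- which(dimnames(p)[[3]] == "POz")
  fpz <- which(dimnames(p)[[3]] == "Fp1")
  expect_lt(mean(p[, , poz, late]), -0.2)
  expect_gt(mean(p[, , poz, late]), -Inf)
  expect_gt(mean(p[, , fpz, late]), mean(p[, , poz, late]))
})

test_that("raw oscillations put their energy at the carrier frequency", {
  raw <- generate_raw_oscillations(3, c(Cz = 0.5), band = c(32, 100),
                                   carrier_hz = 40, noise_sd = 0, seed = 16)
  x <- raw$signal[1, , 1]
  n <- length(x)
  fs <- 500
  spec <- abs(fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  peak <- freqs[which.max(spec[freqs <= fs / 2])]
  expect_lt(abs(peak - 40), 1.5)
  # nyquist guard
  expect_error(generate_raw_oscillations(1, c(Cz = 0), band = c(32, 300)),
               "Nyquist")
  expect_error(generate_raw_oscillations(1, c(Cz = 0), sampling_rate = 100),
               "250")
})

test_that("doubling the envelope quadruples band power (Parseval)", {
  r1 <- generate_raw_oscillations(1, c(Cz = 0), carrier_hz = 40, amp = 1,
                                  noise_sd = 0, seed = 17)
  r2 <- generate_raw_oscillations(1, c(Cz = 0), carrier_hz = 40, amp = 2,
                                  noise_sd = 0, seed = 17)
  p1 <- sum(r1$signal^2)
  p2 <- sum(r2$signal^2)
  expect_equal(p2 / p1, 4, tolerance = 1e-6)
})
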