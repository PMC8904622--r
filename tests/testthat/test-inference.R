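# Reparameterization, drift assembly, convergence diagnostics, sampler
# correctness, and small-scale fitting contracts.

test_that("offset-from-first transform matches its definition and inverts", {
  expect_equal(cumulative_transform(c(1, 0.5, 0.2, 0, 0, 0)),
               c(1, 1.5, 1.2, 1, 1, 1))
  expect_equal(cumulative_transform(c(2, 0, 0, 0, 0, 0)), rep(2, 6))
  set.seed(61)
  for (r in 1:20) {
    x <- rnorm(6)
    expect_equal(cumulative_inverse(cumulative_transform(x)), x,
                 tolerance = 1e-12)
    expect_equal(cumulative_transform(cumulative_inverse(x)), x,
                 tolerance = 1e-12)
  }
})

test_that("drift assembly is the exact linear combination", {
  expect_equal(assemble_drift(2.0), 2.0)
  expect_equal(assemble_drift(2, 0.3, list(padua = -0.5),
                              list(padua = 1)), 1.8)
  # centered covariate makes the symptom term vanish
  expect_equal(assemble_drift(2, 0, list(padua = -0.5), list(padua = 0)), 2)
  expect_error(assemble_drift(2, 0, list(padua = -0.5), list()), "missing")
})

test_that("split R-hat is ~1 for iid draws and large for shifted chains", {
  set.seed(62)
  x <- matrix(rnorm(4 * 1000), 4, 1000)
  expect_lt(abs(split_rhat(x) - 1), 0.02)
  # chains offset by 5 SD: verify against the split-R-hat formula directly
  y <- x + c(0, 5, 0, 5)
  r <- split_rhat(y)
  expect_gt(r, 2)
  halves <- rbind(y[, 1:500], y[, 501:1000])
  W <- mean(apply(halves, 1, var))
  B <- 500 * var(rowMeans(halves))
  expect_equal(r, sqrt((499 / 500 * W + B / 500) / W), tolerance = 1e-12)
  # constant parameter: undefined, flagged as NA
  expect_true(is.na(split_rhat(matrix(1, 2, 100))))
  arr <- array(rnorm(2 * 100 * 2), c(2, 100, 2))
  arr[, , 2] <- 3.14
  d <- diagnose(arr)
  expect_true(is.na(d$rhat[2]))
  expect_false(is.na(d$rhat[1]))
})

test_that("diagnose requires at least two chains", {
  arr <- array(rnorm(100), c(1, 100, 1))
  expect_error(diagnose(arr), "2 chains")
})

test_that("the NUTS engine samples a correlated Gaussian correctly", {
  set.seed(63)
  d <- driftband:::.nuts_gauss_check_cpp(4, 0.7, 500, 3000)
  expect_equal(colMeans(d), rep(0, 4), tolerance = 0.1)
  expect_equal(apply(d, 2, sd), rep(1, 4), tolerance = 0.1)
  expect_equal(cor(d[, 1], d[, 2]), 0.7, tolerance = 0.08)
  expect_equal(cor(d[, 3], d[, 4]), 0.7, tolerance = 0.08)
  expect_lt(abs(cor(d[, 1], d[, 3])), 0.08)
})

test_that("identical seed and data give identical draws", {
  gt <- truth_behavior_only()
  co <- tiny_cohort(4, gt, seed = 64)
  tr <- tiny_trials(co, gt, n_per_cond = 8, seed = 65)
  f1 <- fit_ddm(tr, "behavior_only", chains = 2, warmup = 60, iter = 60,
                seed = 99)
  f2 <- fit_ddm(tr, "behavior_only", chains = 2, warmup = 60, iter = 60,
                seed = 99)
  expect_identical(f1$draws, f2$draws)
})

test_that("variant contracts: covariates must match the variant", {
  gt <- truth_behavior_only()
  co <- tiny_cohort(4, gt, seed = 66)
  tr <- tiny_trials(co, gt, n_per_cond = 4, seed = 67)
  expect_error(fit_ddm(tr, "symptoms"), "covariates")
  expect_error(fit_ddm(tr, "full", covariates = list(
    scores = data.frame(subject = co$subject_id,
                        padua_z = rnorm(4), worry_z = rnorm(4)))),
    "gamma_z")
  expect_error(fit_ddm(tr[tr$subject == co$subject_id[1], ],
                       "behavior_only"), "2 subjects")
})

test_that("neural regression recovers intercepts analytically when null", {
  # with null covariates the posterior intercept approaches the condition
  # mean of the slopes (the least-squares solution)
  set.seed(68)
  S <- 40
  y <- matrix(rnorm(S * 6, mean = rep(c(1, 2, -1, 0, 3, 0.5), each = S),
                    sd = 0.3), S, 6)
  sc <- data.frame(padua_z = rnorm(S), worry_z = rnorm(S))
  fit <- fit_neural_regression(y, sc, chains = 2, warmup = 250, iter = 400,
                               seed = 69)
  m <- draws_matrix(fit)
  for (cc in 1:6) {
    expect_equal(median(m[, paste0("b0_c", cc)]), mean(y[, cc]),
                 tolerance = 0.12)
  }
  # null coefficients: CIs contain 0 for most condition/coefficient pairs
  cover <- 0
  for (cc in 1:6) for (st in c("b_padua_c", "b_worry_c")) {
    s <- summarize_effect(fit, paste0(st, cc))
    cover <- cover + (s$ci_low <= 0 && s$ci_high >= 0)
  }
  expect_gte(cover, 10)
  expect_error(fit_neural_regression(y[1:2, ], sc[1:2, ]), "3 subjects")
})

test_that("posterior draws round-trip through the tidy CSV writer", {
  gt <- truth_behavior_only()
  co <- tiny_cohort(4, gt, seed = 70)
  tr <- tiny_trials(co, gt, n_per_cond = 4, seed = 71)
  fit <- fit_ddm(tr, "behavior_only", chains = 2, warmup = 40, iter = 30,
                 seed = 72)
  path <- tempfile(fileext = ".csv")
  write_draws(fit, path)
  back <- read_draws(path)
  expect_equal(unname(back), unname(fit$draws), tolerance = 1e-6)
  unlink(c(path, sub("\\.csv$", "_diagnostics.csv", path)))
})
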