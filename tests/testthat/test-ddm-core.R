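# Wiener first-passage-time machinery: analytic identities, oracles,
# numerical contracts.

test_that("zero-drift symmetric start splits mass and densities equally", {
  p <- ddm_params(0, 1.4, 0.25)
  rts <- c(0.3, 0.5, 0.9, 2)
  expect_equal(wfpt_log_density(rts, "upper", p),
               wfpt_log_density(rts, "lower", p))
  expect_equal(choice_probability(p), 0.5)
})

test_that("density vanishes at the non-decision time and is -Inf below it", {
  p <- ddm_params(1.2, 1.1, 0.3)
  expect_identical(wfpt_log_density(0.3, "upper", p), -Inf)
  expect_identical(wfpt_log_density(0.1, "upper", p), -Inf)
  # just above ndt the density is tiny but finite on the log scale
  expect_lt(exp(wfpt_log_density(0.3 + 1e-5, "upper", p)), 1e-8)
})

test_that("total mass is 1 and splits by the closed-form choice probability", {
  for (pars in list(ddm_params(1.5, 1.2, 0.3), ddm_params(-0.8, 1.6, 0.2),
                    ddm_params(0.3, 0.9, 0.4))) {
    up <- wfpt_cdf(pars, "upper", t_grid = seq(1e-4, 30, 1e-3) + pars$ndt)
    lo <- wfpt_cdf(pars, "lower", t_grid = seq(1e-4, 30, 1e-3) + pars$ndt)
    expect_equal(max(up$cdf) + max(lo$cdf), 1, tolerance = 1e-4)
    expect_equal(max(up$cdf), choice_probability(pars), tolerance = 1e-4)
  }
})

test_that("choice probability has the correct limits and simulation agrees", {
  expect_equal(choice_probability(ddm_params(50, 2, 0.3)), 1, tolerance = 1e-6)
  expect_equal(choice_probability(ddm_params(-50, 2, 0.3)), 0,
               tolerance = 1e-6)
  p <- ddm_params(1.5, 1.2, 0.3)
  s <- simulate_trials(p, 5e4, seed = 7)
  phat <- mean(s$boundary_hit == "upper")
  se <- sqrt(phat * (1 - phat) / 5e4)
  expect_lt(abs(phat - choice_probability(p)), 3 * se + 1e-3)
})

test_that("analytic gradient matches central finite differences", {
  for (pars in list(ddm_params(1.5, 1.2, 0.3), ddm_params(-0.5, 0.8, 0.2))) {
    for (hit in c("upper", "lower")) {
      rt <- 0.85
      g <- wfpt_log_density_grad(rt, hit, pars)
      for (i in seq_along(c("drift", "boundary", "ndt"))) {
        nm <- c("drift", "boundary", "ndt")[i]
        e <- 1e-6
        pp <- pm <- pars
        pp[[nm]] <- pp[[nm]] + e
        pm[[nm]] <- pm[[nm]] - e
        fd <- (wfpt_log_density(rt, hit, pp) -
                 wfpt_log_density(rt, hit, pm)) / (2 * e)
        expect_equal(unname(g[1, i]), fd, tolerance = 1e-5)
      }
    }
  }
})

test_that("small-time and large-time expansions agree where they overlap", {
  # force each expansion by scaling normalized time around the switch point
  # and compare against high-precision evaluation: density as a function of
  # rt must be smooth through the internal switching region
  p <- ddm_params(1, 1, 0)
  rts <- seq(0.05, 3, by = 1e-3)
  ld <- wfpt_log_density(rts, "lower", p)
  d2 <- diff(diff(exp(ld)))
  # a discontinuity at the switch would show as an isolated second-difference
  # spike orders of magnitude above the smooth curvature scale
  expect_lt(max(abs(d2)), 1e-3)
  expect_true(all(is.finite(ld)))
})

test_that("log-density is continuous in parameters (no kinks)", {
  base <- ddm_params(1.2, 1.3, 0.25)
  for (nm in c("drift", "boundary", "ndt")) {
    grid <- seq(-0.05, 0.05, length.out = 201)
    vals <- vapply(grid, function(d) {
      pp <- base
      pp[[nm]] <- pp[[nm]] + d
      wfpt_log_density(0.8, "upper", pp)
    }, numeric(1))
    expect_lt(max(abs(diff(diff(vals)))), 1e-4)
  }
})

test_that("simulated trials behave like the model", {
  # near-zero boundary: immediate absorption, rt collapses to ndt
  s <- simulate_trials(ddm_params(1, 0.001, 0.3), 100, seed = 1)
  expect_true(all(abs(s$rt_s - 0.3) < 0.01))
  # higher drift gives faster decisions
  s2 <- simulate_trials(ddm_params(2, 1, 0.2), 5000, seed = 2)
  s4 <- simulate_trials(ddm_params(4, 1, 0.2), 5000, seed = 3)
  expect_gt(mean(s2$rt_s), mean(s4$rt_s))
  # determinism under a fixed seed
  expect_identical(simulate_trials(ddm_params(1.5, 1.2, 0.3), 50, seed = 9),
                   simulate_trials(ddm_params(1.5, 1.2, 0.3), 50, seed = 9))
})

test_that("density matches a large simulation (binned CDF)", {
  p <- ddm_params(1.5, 1.2, 0.3)
  n <- 2e5
  s <- simulate_trials(p, n, seed = 11)
  ref <- wfpt_cdf(p, "upper", t_grid = seq(1e-4, 9.7, by = 2e-3) + p$ndt)
  emp <- stats::ecdf(s$rt_s[s$boundary_hit == "upper"])(ref$t) *
    mean(s$boundary_hit == "upper")
  expect_lt(max(abs(emp - ref$cdf)), 0.008)
})

test_that("parameter validation enforces the type invariants", {
  expect_error(ddm_params(1, -1, 0.3))
  expect_error(ddm_params(1, 1, -0.1))
  expect_error(ddm_params(1, 1, 0.3, start_frac = 1.2))
})
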