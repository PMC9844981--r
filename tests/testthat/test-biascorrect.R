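# Bias correction factor arithmetic and Monte Carlo prior propagation.

test_that("bias correction factor reproduces the worked example and null cases", {
  expect_equal(round(bias_correction_factor(
    bias_parameters(p1 = 0.3, p0 = 0.15, rr_uy = 2.35)), 2), 1.17)
  # equal prevalences cancel
  expect_equal(bias_correction_factor(bias_parameters(0.2, 0.2, 3)), 1)
  # null confounder effect
  expect_equal(bias_correction_factor(bias_parameters(0.4, 0.1, 1)), 1)
})

test_that("adjust_rr divides by the correction factor and is scale-equivariant", {
  bp <- bias_parameters(0.3, 0.15, 2.35)
  res <- adjust_rr(0.96, bp)
  expect_equal(round(res$adjusted_rr, 2), 0.82)
  expect_equal(res$adjusted_rr * res$bcf, res$unadjusted_rr)
  # hand arithmetic: BCF = (2*0.5 + 0.5)/(2*0 + 1) = 1.5
  expect_equal(adjust_rr(1.50, bias_parameters(0.5, 0, 2.0))$adjusted_rr, 1.0)
  # null bias parameters leave the RR untouched
  expect_equal(adjust_rr(0.7, bias_parameters(0.2, 0.2, 3))$adjusted_rr, 0.7)
  for (c_ in c(0.5, 2, 10))
    expect_equal(adjust_rr(c_ * 0.96, bp)$adjusted_rr,
                 c_ * res$adjusted_rr)
  expect_error(adjust_rr(-1, bp), "positive")
})

test_that("BCF is monotone in the prevalences and symmetric under swapping them", {
  grid <- expand.grid(p1 = c(0.1, 0.3, 0.6), p0 = c(0.05, 0.2, 0.5),
                      rr = c(0.4, 2.5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    up <- bias_correction_factor(bias_parameters(g$p1 + 0.05, g$p0, g$rr)) -
      bias_correction_factor(bias_parameters(g$p1, g$p0, g$rr))
    down <- bias_correction_factor(bias_parameters(g$p1, g$p0 + 0.05, g$rr)) -
      bias_correction_factor(bias_parameters(g$p1, g$p0, g$rr))
    if (g$rr > 1) {
      expect_gt(up, 0); expect_lt(down, 0)
    } else {
      expect_lt(up, 0); expect_gt(down, 0)
    }
    expect_equal(
      bias_correction_factor(bias_parameters(g$p1, g$p0, g$rr)) *
        bias_correction_factor(bias_parameters(g$p0, g$p1, g$rr)),
      1)
  }
})

test_that("typical values are arithmetic/geometric means of the elicited limits", {
  tv <- typical_values(expert2_priors())
  expect_equal(tv$p1, 0.3)
  expect_equal(tv$p0, 0.15)
  expect_equal(round(tv$rr_uy, 2), 2.35)
  # near-degenerate interval pins the typical value at the midpoint
  ps <- build_expert_prior_set(list(
    elicited_interval("P1", 0.1999, 0.2001),
    elicited_interval("P0", 0.0999, 0.1001),
    elicited_interval("RR_UY", 1.1, 5)))
  expect_equal(typical_values(ps)$p1, 0.2, tolerance = 1e-10)
})

test_that("Monte Carlo propagation reproduces the published adjusted medians", {
  mc1 <- monte_carlo_adjust(0.96, expert1_priors(), n_draws = 1e5, seed = 1)
  expect_equal(round(mc1$median, 2), 0.95)
  mc2 <- monte_carlo_adjust(0.96, expert2_priors(), n_draws = 1e5, seed = 1)
  expect_equal(mc2$median, 0.82, tolerance = 0.025)
  expect_lt(mc2$ci95[1L], mc2$median)
  expect_gt(mc2$ci95[2L], mc2$median)
})

test_that("Monte Carlo propagation is reproducible and collapses for tight priors", {
  ps <- expert2_priors()
  a <- monte_carlo_adjust(0.96, ps, n_draws = 2000, seed = 42)
  b <- monte_carlo_adjust(0.96, ps, n_draws = 2000, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_error(monte_carlo_adjust(0.96, ps, n_draws = 10), "at least 1000")
  # p1 == p0 priors make the BCF identically 1
  null_ps <- build_expert_prior_set(list(
    elicited_interval("P1", 0.199, 0.201),
    elicited_interval("P0", 0.199, 0.201),
    elicited_interval("RR_UY", 1.1, 5)))
  expect_equal(monte_carlo_adjust(1.0, null_ps, 5000, seed = 2)$median, 1.0,
               tolerance = 0.005)
  # tight priors: the draw median converges to the plug-in at prior medians
  tight <- build_expert_prior_set(list(
    elicited_interval("P1", 0.298, 0.302),
    elicited_interval("P0", 0.148, 0.152),
    elicited_interval("RR_UY", 2.34, 2.36)))
  plug <- adjust_rr(0.96, bias_parameters(
    qbeta(0.5, tight$p1_prior$alpha, tight$p1_prior$beta),
    qbeta(0.5, tight$p0_prior$alpha, tight$p0_prior$beta),
    exp(tight$log_rr_prior$mu)))$adjusted_rr
  mc <- monte_carlo_adjust(0.96, tight, n_draws = 1e5, seed = 3)
  expect_equal(mc$median, plug, tolerance = 5e-4)
})

test_that("stochastically larger p1 priors shrink the adjusted RR (rr_uy > 1)", {
  meds <- vapply(list(c(0.10, 0.20), c(0.20, 0.35), c(0.35, 0.55)),
                 function(iv) {
    ps <- build_expert_prior_set(list(
      elicited_interval("P1", iv[1L], iv[2L]),
      elicited_interval("P0", 0.05, 0.10),
      elicited_interval("RR_UY", 1.5, 3)))
    monte_carlo_adjust(1.0, ps, n_draws = 2e4, seed = 9)$median
  }, numeric(1L))
  expect_true(all(diff(meds) < 0))
})
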