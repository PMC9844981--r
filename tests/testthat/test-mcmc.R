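# Batch-means MCSE and the Metropolis-within-Gibbs bias-analysis sampler.

test_that("batch-means MCSE matches closed forms for iid and constant draws", {
  set.seed(1)
  expect_equal(mcse(rnorm(10000)), 0.01, tolerance = 0.2)
  expect_equal(mcse(rep(3.7, 500)), 0)
  expect_error(mcse(rnorm(50)), "at least 100")
})

test_that("batch-means MCSE tracks the analytic AR(1) asymptotic variance", {
  set.seed(2)
  rho <- 0.6; n <- 50000L
  x <- as.numeric(stats::arima.sim(list(ar = rho), n))
  # asymptotic SE of the mean: sqrt(var(x) * (1+rho)/(1-rho) / n)
  se_true <- sqrt(1 / (1 - rho^2) * (1 + rho) / (1 - rho) / n)
  expect_equal(mcse(x), se_true, tolerance = 0.2)
})

test_that("precision Gibbs step matches its analytic gamma full conditional", {
  # freeze the coefficients and random intercepts; the precision draws are
  # then iid from Gamma(shape + n/2, rate + sum(b^2)/2)
  set.seed(31)
  n_cl <- 40L
  b <- rnorm(n_cl, 0, 0.5)
  X <- cbind(1, rbinom(200, 1, 0.5))
  y <- rbinom(200, 1, 0.3)
  cl <- rep(seq_len(n_cl), each = 5L)
  run <- biasbayes:::.ri_poisson_chain(
    X, as.numeric(y), as.integer(cl), n_cl, 0L, 4000L,
    1e6, 0.001, 0.001, c(0, 0), b, 0.25, c(0.1, 0.1), 0.3,
    FALSE, FALSE, FALSE)
  prec <- 1 / run$tau
  ks <- stats::ks.test(prec, stats::pgamma,
                       shape = 0.001 + n_cl / 2,
                       rate = 0.001 + sum(b^2) / 2)
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate exposure posterior reproduces plain prior propagation", {
  ps <- expert2_priors()
  post <- run_bias_mcmc(NULL, ps, fixed_unadjusted_rr = 0.96,
                        control = mcmc_control(n_burnin = 0L,
                                               n_iter_initial = 5000L,
                                               n_iter_max = 5000L,
                                               seed = 101))
  mc <- monte_carlo_adjust(0.96, ps, n_draws = 5000, seed = 202)
  ks <- suppressWarnings(stats::ks.test(post$draws, mc$draws))
  expect_gt(ks$p.value, 0.01)
  expect_equal(post$median, mc$median, tolerance = 0.02)
})

test_that("null bias priors leave the posterior RR unadjusted", {
  null_ps <- build_expert_prior_set(list(
    elicited_interval("P1", 0.199, 0.201),
    elicited_interval("P0", 0.199, 0.201),
    elicited_interval("RR_UY", 1.1, 5)))
  post <- run_bias_mcmc(NULL, null_ps, fixed_unadjusted_rr = 1.0,
                        control = mcmc_control(seed = 11))
  expect_equal(post$median, 1.0, tolerance = 0.005)
})

test_that("the sampler's unadjusted RR agrees with GEE on a large cohort", {
  co <- simulate_cohort(cohort_spec(n_subjects = 1200L, seed = 51))
  rec <- build_analysis_records(co$visits)
  gee <- fit_gee_poisson(rec)
  post <- run_bias_mcmc(rec, expert1_priors(),
                        control = mcmc_control(seed = 52))
  log_draws <- log(post$unadjusted_draws)
  expect_lt(abs(median(log_draws) - log(gee$exposure_rr)),
            2 * sqrt(mcse(log_draws)^2 + gee$exposure_se_log^2) + 0.02)
})

test_that("chains from different seeds agree within Monte Carlo error", {
  co <- simulate_cohort(cohort_spec(n_subjects = 250L, seed = 61))
  rec <- build_analysis_records(co$visits)
  ps <- expert1_priors()
  p1 <- run_bias_mcmc(rec, ps, covariates = character(0),
                      control = mcmc_control(seed = 62))
  p2 <- run_bias_mcmc(rec, ps, covariates = character(0),
                      control = mcmc_control(seed = 63))
  expect_lt(abs(p1$median - p2$median), 3 * (p1$mcse + p2$mcse) + 0.01)
  # same seed: identical draws
  p3 <- run_bias_mcmc(rec, ps, covariates = character(0),
                      control = mcmc_control(seed = 62))
  expect_identical(p1$draws, p3$draws)
})

test_that("stochastically larger p1 priors yield stochastically smaller adjusted RRs", {
  lo <- build_expert_prior_set(list(
    elicited_interval("P1", 0.10, 0.20),
    elicited_interval("P0", 0.05, 0.10),
    elicited_interval("RR_UY", 1.5, 3)))
  hi <- build_expert_prior_set(list(
    elicited_interval("P1", 0.35, 0.55),
    elicited_interval("P0", 0.05, 0.10),
    elicited_interval("RR_UY", 1.5, 3)))
  post_lo <- run_bias_mcmc(NULL, lo, fixed_unadjusted_rr = 1,
                           control = mcmc_control(seed = 71))
  post_hi <- run_bias_mcmc(NULL, hi, fixed_unadjusted_rr = 1,
                           control = mcmc_control(seed = 72))
  qs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(quantile(post_hi$draws, qs) < quantile(post_lo$draws, qs)))
})

test_that("mcmc_control validates its invariants", {
  expect_error(mcmc_control(n_burnin = 4000, n_iter_initial = 4000))
  expect_error(mcmc_control(mcse_fraction_stop = 1.5))
  expect_error(run_bias_mcmc(NULL, expert1_priors()), "nonempty")
})
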