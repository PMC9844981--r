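# Lagged record construction, censoring, and the GEE / random-effect fits.

test_that("analysis records pair consecutive visits with a one-visit lag", {
  # 3 visits, HIV-positive at the third: only the (v1 -> v2) pair survives
  v <- toy_visits(1, exposure = c(1, 0, 1), nbt = c(0, 1, 0),
                  hiv = c(0, 0, 1))
  rec <- build_analysis_records(v)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$exposure, 1)
  expect_equal(rec$outcome, 1)

  # single visit: nothing to pair
  expect_equal(nrow(build_analysis_records(toy_visits(2, 1, 0))), 0L)

  # five clean visits: k - 1 records, outcome lagged one visit behind exposure
  v5 <- toy_visits(3, exposure = c(1, 1, 0, 0, 1), nbt = c(0, 1, 1, 0, 1))
  rec5 <- build_analysis_records(v5)
  expect_equal(nrow(rec5), 4L)
  expect_equal(rec5$exposure, c(1, 1, 0, 0))
  expect_equal(rec5$outcome, c(1, 1, 0, 1))
})

test_that("no record uses data at or after the first HIV-positive visit", {
  # positive at visit 2 of 6: even later HIV-negative-looking rows are cut
  v <- toy_visits(1, exposure = rep(1, 6), nbt = rep(1, 6),
                  hiv = c(0, 1, 1, 1, 1, 1))
  expect_equal(nrow(build_analysis_records(v)), 0L)
  # positive at visit 4 of 6: pairs (1,2) and (2,3) survive
  v2 <- toy_visits(2, exposure = rep(1, 6), nbt = rep(0, 6),
                   hiv = c(0, 0, 0, 1, 0, 0))
  expect_equal(nrow(build_analysis_records(v2)), 2L)
})

test_that("record construction validates ordering and reports dropped missingness", {
  bad <- toy_visits(1, c(1, 0), c(0, 1))
  bad$visit_index <- c(2L, 1L)
  expect_error(build_analysis_records(bad), "strictly increasing")
  dup <- toy_visits(1, c(1, 0), c(0, 1))
  dup$visit_index <- c(1L, 1L)
  expect_error(build_analysis_records(dup), "duplicated")

  v <- toy_visits(1, exposure = c(1, NA, 0, 1), nbt = c(0, 1, 1, 0))
  expect_message(rec <- build_analysis_records(v), "dropped 1")
  expect_equal(nrow(rec), 2L)
})

test_that("independence GEE coincides with Poisson GLM plus cluster-robust sandwich", {
  skip_if_not_installed("sandwich")
  co <- simulate_cohort(cohort_spec(n_subjects = 150L, seed = 3))
  rec <- build_analysis_records(co$visits)
  gee <- fit_gee_poisson(rec, working_correlation = "independence")
  glmfit <- stats::glm(
    outcome ~ exposure + age + gender_female + gender_transgender +
      education_lths + incarcerated_baseline + incarcerated_recent +
      ever_tested_baseline,
    data = rec, family = stats::poisson(),
    control = stats::glm.control(epsilon = 1e-14, maxit = 100L))
  expect_equal(unname(gee$coefficients), unname(coef(glmfit)),
               tolerance = 1e-8)
  vc <- sandwich::vcovCL(glmfit, cluster = rec$subject_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(gee$robust_covariance), unname(vc), tolerance = 1e-5)
})

test_that("GEE point estimates are invariant to cluster and record ordering", {
  co <- simulate_cohort(cohort_spec(n_subjects = 120L, seed = 8))
  rec <- build_analysis_records(co$visits)
  fit1 <- fit_gee_poisson(rec)
  set.seed(99)
  fit2 <- fit_gee_poisson(rec[sample(nrow(rec)), ])
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-8)
  expect_equal(fit1$robust_covariance, fit2$robust_covariance,
               tolerance = 1e-8)
})

test_that("GEE recovers the generator's marginal risk ratio", {
  # null confounder (rr_uy = 1): the marginal RR is the generator's truth
  co <- simulate_cohort(cohort_spec(n_subjects = 4000L, rr_uy = 1,
                                    true_rr_exposure = 1,
                                    p1 = 0.3, p0 = 0.15, seed = 21))
  fit <- fit_gee_poisson(build_analysis_records(co$visits))
  expect_equal(fit$exposure_rr, 1, tolerance = 0.05)
  expect_true(fit$ci95[1L] < 1 && 1 < fit$ci95[2L])

  co2 <- simulate_cohort(cohort_spec(n_subjects = 4000L, rr_uy = 1,
                                     true_rr_exposure = 0.8, seed = 22))
  fit2 <- fit_gee_poisson(build_analysis_records(co2$visits))
  expect_equal(fit2$exposure_rr, 0.8, tolerance = 0.06)
})

test_that("GEE confidence intervals attain near-nominal coverage", {
  n_rep <- 300L
  true_rr <- 0.822
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(cohort_spec(n_subjects = 200L, rr_uy = 1,
                                      true_rr_exposure = true_rr,
                                      seed = 5000L + r))
    ci <- fit_gee_poisson(build_analysis_records(co$visits),
                          covariates = character(0))$ci95
    covered[r] <- ci[1L] <= true_rr && true_rr <= ci[2L]
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("GEE fails informatively on degenerate designs", {
  co <- simulate_cohort(cohort_spec(n_subjects = 60L, seed = 5))
  rec <- build_analysis_records(co$visits)
  rec$dup <- rec$exposure
  expect_error(fit_gee_poisson(rec, covariates = "dup"), "rank deficient")
  one <- rec[rec$subject_id == rec$subject_id[1L], ]
  expect_error(fit_gee_poisson(one, covariates = character(0)),
               "2 clusters")
})

test_that("random-effect Poisson ML agrees with plain GLM when clustering is absent", {
  co <- simulate_cohort(cohort_spec(n_subjects = 800L, re_sd = 0, seed = 13))
  rec <- build_analysis_records(co$visits)
  re <- fit_re_poisson_ml(rec, covariates = character(0))
  glmfit <- stats::glm(outcome ~ exposure, data = rec,
                       family = stats::poisson())
  expect_lt(re$re_sd, 0.05)
  expect_equal(unname(re$coefficients), unname(coef(glmfit)),
               tolerance = 1e-4)
})

test_that("random-effect Poisson ML recovers a known intercept variance", {
  # genuine Poisson counts (binary outcomes cannot identify the variance:
  # Bernoulli underdispersion pushes the Poisson-model tau to zero)
  set.seed(17)
  n <- 1200L; k <- 5L
  b <- rnorm(n, 0, 0.4)
  rec <- data.frame(subject_id = rep(seq_len(n), each = k),
                    exposure = rbinom(n * k, 1L, 0.5))
  rec$outcome <- rpois(n * k, exp(-0.5 - 0.2 * rec$exposure +
                                    b[rec$subject_id]))
  re <- fit_re_poisson_ml(rec, covariates = character(0))
  expect_equal(re$re_sd, 0.4, tolerance = 0.1)
  expect_equal(re$exposure_rr, exp(-0.2), tolerance = 0.05)
})
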