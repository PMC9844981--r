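#' @useDynLib biasbayes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Batch-means Monte Carlo standard error
#'
#' MCSE of the sample mean of (possibly autocorrelated) draws by
#' non-overlapping batch means with batch size `floor(sqrt(n))`.
#'
#' @param draws Numeric vector with at least 100 elements.
#' @return The Monte Carlo standard error of the mean.
#' @examples
#' mcse(rnorm(10000))  # about 0.01
#' @export
mcse <- function(draws) {
  n <- length(draws)
  if (n < 100L)
    stop("need at least 100 draws for a batch-means MCSE", call. = FALSE)
  b <- floor(sqrt(n))
  nb <- n %/% b
  bm <- colMeans(matrix(draws[seq_len(nb * b)], nrow = b))
  stats::sd(bm) / sqrt(nb)
}

#' Hyperpriors for the Bayesian random-intercept Poisson model
#'
#' Diffuse defaults: regression coefficients are a priori N(0, 1e6); the
#' random-intercept precision `1/tau` has a Gamma(0.001, 0.001) prior
#' (conditionally conjugate, so it is updated by a Gibbs step).
#'
#' @param coef_mean,coef_variance Normal prior for each coefficient.
#' @param precision_shape,precision_rate Gamma prior for the precision.
#' @return An object of class `"hyper_priors"`.
#' @export
hyper_priors <- function(coef_mean = 0, coef_variance = 1e6,
                         precision_shape = 0.001, precision_rate = 0.001) {
  stopifnot(coef_variance > 0, precision_shape > 0, precision_rate > 0)
  structure(list(coef_mean = coef_mean, coef_variance = coef_variance,
                 precision_shape = precision_shape,
                 precision_rate = precision_rate),
            class = "hyper_priors")
}

#' MCMC run configuration
#'
#' Defaults mirror the analysis protocol: 1000 burn-in iterations, an
#' initial run of 4000 total iterations, then extension in blocks until the
#' Monte Carlo standard error of the adjusted RR falls below
#' `mcse_fraction_stop` times its posterior standard deviation, capped at
#' `n_iter_max` total iterations.
#'
#' @param n_burnin Burn-in iterations (discarded; step sizes adapt here).
#' @param n_iter_initial Total iterations of the first run, burn-in
#'   included; must exceed `n_burnin`.
#' @param n_iter_max Hard cap on total iterations.
#' @param mcse_fraction_stop Convergence criterion as a fraction of the
#'   posterior SD, in (0, 1).
#' @param extend_by Iterations added per extension block.
#' @param seed Optional integer seed.
#' @return An object of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_burnin = 1000L, n_iter_initial = 4000L,
                         n_iter_max = 10000L, mcse_fraction_stop = 0.05,
                         extend_by = 2000L, seed = NULL) {
  stopifnot(n_burnin >= 0L, n_iter_initial > n_burnin,
            n_iter_max >= n_iter_initial, extend_by >= 100L,
            mcse_fraction_stop > 0, mcse_fraction_stop < 1)
  structure(list(n_burnin = as.integer(n_burnin),
                 n_iter_initial = as.integer(n_iter_initial),
                 n_iter_max = as.integer(n_iter_max),
                 mcse_fraction_stop = mcse_fraction_stop,
                 extend_by = as.integer(extend_by), seed = seed),
            class = "mcmc_control")
}

# One call into the compiled chain, continuing from `state` if given.
.run_chain <- function(X, y, cluster, n_cluster, hp, n_burnin, n_keep,
                       state = NULL, adapt = TRUE,
                       update_beta = TRUE, update_b = TRUE) {
  p <- ncol(X)
  if (is.null(state)) {
    beta0 <- tryCatch(stats::glm.fit(X, y, family = stats::poisson())$coefficients,
                      error = function(e) rep(0, p))
    beta0[!is.finite(beta0)] <- 0
    state <- list(beta = beta0, b = rep(0, n_cluster), tau = 0.1,
                  beta_scale = rep(0.1, p), b_scale = 0.3)
  }
  .ri_poisson_chain(X, y, as.integer(cluster), as.integer(n_cluster),
                    as.integer(n_burnin), as.integer(n_keep),
                    hp$coef_variance, hp$precision_shape, hp$precision_rate,
                    state$beta, state$b, state$tau,
                    state$beta_scale, state$b_scale,
                    adapt, update_beta, update_b)
}

#' Bayesian bias analysis by MCMC over the random-intercept Poisson model
#'
#' Samples the posterior of the Gaussian random-intercept Poisson model for
#' the lagged binary outcome (Metropolis random-walk updates for the
#' coefficients and intercepts, a conjugate Gibbs step for the precision),
#' and, for every retained iteration, draws the three bias parameters from
#' the expert priors, forms the bias correction factor, and records the
#' bias-adjusted risk ratio `exp(exposure coefficient) / BCF`. The bias
#' parameters are not identified by the likelihood and are drawn
#' independently of the data. Sampling is extended after the initial run
#' until the batch-means MCSE of the adjusted RR is below
#' `mcse_fraction_stop` of its posterior SD, or `n_iter_max` is reached.
#'
#' @param records Analysis records from [build_analysis_records()]; may be
#'   `NULL` when `fixed_unadjusted_rr` is supplied.
#' @param priors An `"expert_prior_set"`.
#' @param covariates Covariate columns to adjust for.
#' @param hp Hyperpriors from [hyper_priors()].
#' @param control An [mcmc_control()].
#' @param fixed_unadjusted_rr If supplied, the model-sampling stage is
#'   bypassed and this constant plays the role of the per-iteration
#'   unadjusted RR — the degenerate-posterior mode used to validate the
#'   bias-propagation stage against plain Monte Carlo prior propagation.
#' @return An object of class `c("bias_posterior", "posterior_summary")`:
#'   the adjusted-RR draws with median, 95% credible interval (2.5th/97.5th
#'   percentiles), MCSE and a convergence flag, plus `unadjusted_draws`,
#'   `tau_draws`, acceptance rates, and the unadjusted-RR posterior summary.
#' @export
run_bias_mcmc <- function(records, priors, covariates = panel_covariates(),
                          hp = hyper_priors(), control = mcmc_control(),
                          fixed_unadjusted_rr = NULL) {
  stopifnot(inherits(priors, "expert_prior_set"),
            inherits(hp, "hyper_priors"), inherits(control, "mcmc_control"))
  if (!is.null(control$seed)) set.seed(control$seed)

  n_keep0 <- control$n_iter_initial - control$n_burnin
  max_keep <- control$n_iter_max - control$n_burnin

  if (is.null(fixed_unadjusted_rr)) {
    if (is.null(records) || !nrow(records))
      stop("records must be nonempty unless fixed_unadjusted_rr is given",
           call. = FALSE)
    d <- .panel_design(records, covariates)
    n_cluster <- max(d$cluster)
    run <- .run_chain(d$X, d$y, d$cluster, n_cluster, hp,
                      control$n_burnin, n_keep0)
    log_rr <- run$beta[, 2L]
    tau_draws <- run$tau
    accept <- list(beta = run$accept_beta, b = run$accept_b)
    state <- run$state
  } else {
    stopifnot(fixed_unadjusted_rr > 0)
    log_rr <- rep(log(fixed_unadjusted_rr), n_keep0)
    tau_draws <- numeric(0)
    accept <- NULL
    state <- NULL
  }

  bp <- draw_bias_parameters(priors, length(log_rr))
  adj <- exp(log_rr) / bias_correction_factor(bp)

  repeat {
    cur_mcse <- mcse(adj)
    if (cur_mcse < control$mcse_fraction_stop * stats::sd(adj)) {
      converged <- TRUE
      break
    }
    if (length(adj) >= max_keep) {
      converged <- FALSE
      break
    }
    n_more <- min(control$extend_by, max_keep - length(adj))
    if (is.null(fixed_unadjusted_rr)) {
      run <- .run_chain(d$X, d$y, d$cluster, n_cluster, hp,
                        0L, n_more, state = state, adapt = FALSE)
      more_log_rr <- run$beta[, 2L]
      tau_draws <- c(tau_draws, run$tau)
      accept <- list(beta = run$accept_beta, b = run$accept_b)
      state <- run$state
    } else {
      more_log_rr <- rep(log(fixed_unadjusted_rr), n_more)
    }
    more_bp <- draw_bias_parameters(priors, n_more)
    adj <- c(adj, exp(more_log_rr) / bias_correction_factor(more_bp))
    log_rr <- c(log_rr, more_log_rr)
  }

  out <- posterior_summary(adj, expert_id = priors$expert_id,
                           n_iter_used = control$n_burnin + length(adj),
                           converged = converged)
  out$unadjusted_draws <- exp(log_rr)
  out$unadjusted_rr <- stats::median(out$unadjusted_draws)
  out$tau_draws <- tau_draws
  out$accept <- accept
  class(out) <- c("bias_posterior", class(out))
  out
}
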