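#' Elicited 95% prior interval for a bias parameter
#'
#' Container for one expert's 95% prior interval for one of the three bias
#' parameters: `P1` (prevalence of the unmeasured confounder among the
#' exposed), `P0` (prevalence among the unexposed), or `RR_UY` (risk ratio of
#' the confounder on the outcome).
#'
#' @param parameter One of `"P1"`, `"P0"`, `"RR_UY"`.
#' @param lower,upper Positive reals with `lower < upper`. For `P1`/`P0` the
#'   bounds must lie strictly inside (0, 1); for `RR_UY` they are on the
#'   ratio scale and may exceed 1.
#' @param expert_id Label for the expert the interval came from.
#' @return An object of class `"elicited_interval"`.
#' @examples
#' elicited_interval("P1", 0.025, 0.095, expert_id = "expert1")
#' @export
elicited_interval <- function(parameter, lower, upper, expert_id = "expert") {
  parameter <- match.arg(parameter, c("P1", "P0", "RR_UY"))
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L)
  if (!(lower > 0))
    stop("'lower' must be positive, got ", lower, call. = FALSE)
  if (!(lower < upper))
    stop("need lower < upper, got [", lower, ", ", upper, "]", call. = FALSE)
  if (parameter %in% c("P1", "P0") && upper >= 1)
    stop("proportion interval for ", parameter,
         " must lie strictly inside (0, 1)", call. = FALSE)
  structure(
    list(parameter = parameter, lower = lower, upper = upper,
         expert_id = expert_id),
    class = "elicited_interval"
  )
}

#' @export
print.elicited_interval <- function(x, ...) {
  cat(sprintf("Elicited 95%% interval: %s in [%g, %g] (%s)\n",
              x$parameter, x$lower, x$upper, x$expert_id))
  invisible(x)
}

# Sum of squared errors between the 2.5th/97.5th beta percentiles and the
# target interval; parametrised on the log scale so the search is unconstrained.
.beta_percentile_sse <- function(log_ab, target) {
  a <- exp(log_ab[1L]); b <- exp(log_ab[2L])
  if (!is.finite(a) || !is.finite(b)) return(2)
  q <- suppressWarnings(stats::qbeta(c(0.025, 0.975), a, b))
  if (anyNA(q)) return(2)
  sum((q - target)^2)
}

#' Fit a beta prior to an elicited 95% proportion interval
#'
#' Finds `(alpha, beta)` such that the 2.5th and 97.5th percentiles of
#' `Beta(alpha, beta)` match the elicited interval: a deterministic coarse
#' grid over the effective prior sample size `alpha + beta` (log-spaced over
#' \[0.5, 5000\], mean anchored at the interval midpoint) seeds a
#' derivative-free Nelder-Mead refinement of the summed squared percentile
#' error.
#'
#' @param interval An [elicited_interval()] for `P1` or `P0`.
#' @param tolerance Maximum allowed absolute error, on the probability scale,
#'   of each fitted percentile relative to the elicited bound.
#' @return An object of class `"beta_prior"`: a list with `alpha`, `beta`,
#'   the achieved `q025`/`q975`, and the source `interval`.
#' @examples
#' fit_beta_from_interval(elicited_interval("P1", 0.025, 0.095))
#' @export
fit_beta_from_interval <- function(interval, tolerance = 1e-3) {
  stopifnot(inherits(interval, "elicited_interval"))
  if (!interval$parameter %in% c("P1", "P0"))
    stop("beta fitting applies to proportion parameters (P1, P0), not ",
         interval$parameter, call. = FALSE)
  lower <- interval$lower; upper <- interval$upper
  mid <- (lower + upper) / 2

  best <- NULL
  for (n0 in exp(seq(log(0.5), log(5000), length.out = 60L))) {
    start <- log(c(mid * n0, (1 - mid) * n0))
    opt <- stats::optim(start, .beta_percentile_sse,
                        target = c(lower, upper),
                        method = "Nelder-Mead",
                        control = list(maxit = 2000L, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  alpha <- exp(best$par[1L]); beta <- exp(best$par[2L])
  q025 <- stats::qbeta(0.025, alpha, beta)
  q975 <- stats::qbeta(0.975, alpha, beta)
  if (abs(q025 - lower) > tolerance || abs(q975 - upper) > tolerance)
    stop(sprintf(
      "no beta distribution matches [%g, %g] within tolerance %g (best fit: alpha=%.4g, beta=%.4g, percentiles [%.4g, %.4g])",
      lower, upper, tolerance, alpha, beta, q025, q975), call. = FALSE)
  structure(
    list(alpha = alpha, beta = beta, q025 = q025, q975 = q975,
         interval = interval),
    class = "beta_prior"
  )
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta(alpha = %.2f, beta = %.2f) prior for %s, 95%% interval [%.4g, %.4g]\n",
              x$alpha, x$beta, x$interval$parameter, x$q025, x$q975))
  invisible(x)
}

#' Fit a normal prior for the log risk ratio from an elicited interval
#'
#' Converts an elicited 95% interval for a risk ratio into a normal prior on
#' its logarithm: the mean is the average of the log bounds and the standard
#' deviation is the log-interval width divided by 3.92 (two 1.96 half-widths),
#' so `exp(mu +/- 1.96 * sigma)` recovers the elicited bounds exactly.
#'
#' @param interval An [elicited_interval()] for `RR_UY` (any interval with
#'   positive bounds is accepted).
#' @return An object of class `"lognormal_rr_prior"`: a list with `mu`,
#'   `sigma` (both on the log scale) and the source `interval`.
#' @examples
#' fit_lognormal_rr_from_interval(elicited_interval("RR_UY", 1.1, 2.2))
#' @export
fit_lognormal_rr_from_interval <- function(interval) {
  stopifnot(inherits(interval, "elicited_interval"))
  mu <- (log(interval$lower) + log(interval$upper)) / 2
  sigma <- (log(interval$upper) - log(interval$lower)) / 3.92
  structure(
    list(mu = mu, sigma = sigma, interval = interval),
    class = "lognormal_rr_prior"
  )
}

#' @export
print.lognormal_rr_prior <- function(x, ...) {
  cat(sprintf("ln(RR) ~ Normal(mu = %.2f, sigma = %.2f); RR 95%% interval [%.3g, %.3g]\n",
              x$mu, x$sigma, exp(x$mu - 1.96 * x$sigma), exp(x$mu + 1.96 * x$sigma)))
  invisible(x)
}

#' Build the full prior set for one expert
#'
#' Combines exactly one elicited interval per bias parameter into the fitted
#' prior set used downstream: beta priors for `P1` and `P0`, and a normal
#' prior for `ln(RR_UY)`. The source intervals are retained because the
#' typical-value plug-in is defined on interval endpoints, not on the fitted
#' distributions.
#'
#' @param intervals A list of three [elicited_interval()] objects, one for
#'   each of `P1`, `P0`, `RR_UY`.
#' @param expert_id Label; defaults to the `expert_id` of the first interval.
#' @param tolerance Passed to [fit_beta_from_interval()].
#' @return An object of class `"expert_prior_set"` with elements `expert_id`,
#'   `p1_prior`, `p0_prior`, `log_rr_prior`, and `intervals`.
#' @examples
#' build_expert_prior_set(list(
#'   elicited_interval("P1", 0.20, 0.40),
#'   elicited_interval("P0", 0.10, 0.20),
#'   elicited_interval("RR_UY", 1.1, 5)
#' ), expert_id = "expert2")
#' @export
build_expert_prior_set <- function(intervals, expert_id = NULL,
                                   tolerance = 1e-3) {
  if (!is.list(intervals) ||
      !all(vapply(intervals, inherits, logical(1L), "elicited_interval")))
    stop("'intervals' must be a list of elicited_interval objects",
         call. = FALSE)
  params <- vapply(intervals, `[[`, character(1L), "parameter")
  if (anyDuplicated(params))
    stop("duplicated bias parameter(s): ",
         paste(unique(params[duplicated(params)]), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(c("P1", "P0", "RR_UY"), params)
  if (length(missing))
    stop("missing interval(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  by_param <- stats::setNames(intervals, params)
  if (is.null(expert_id)) expert_id <- intervals[[1L]]$expert_id
  structure(
    list(
      expert_id    = expert_id,
      p1_prior     = fit_beta_from_interval(by_param$P1, tolerance),
      p0_prior     = fit_beta_from_interval(by_param$P0, tolerance),
      log_rr_prior = fit_lognormal_rr_from_interval(by_param$RR_UY),
      intervals    = by_param
    ),
    class = "expert_prior_set"
  )
}

#' @export
print.expert_prior_set <- function(x, ...) {
  cat("Bias-parameter priors for", x$expert_id, "\n")
  cat("  P1:    "); print(x$p1_prior)
  cat("  P0:    "); print(x$p0_prior)
  cat("  RR_UY: "); print(x$log_rr_prior)
  invisible(x)
}

#' Read expert prior intervals from a YAML config
#'
#' The config maps expert labels to three entries, e.g.
#' ```yaml
#' expert1:
#'   - {parameter: P1, lower: 0.025, upper: 0.095}
#'   - {parameter: P0, lower: 0.01,  upper: 0.06}
#'   - {parameter: RR_UY, lower: 1.1, upper: 2.2}
#' ```
#'
#' @param path Path to the YAML file.
#' @param tolerance Passed to [fit_beta_from_interval()].
#' @return A named list of `"expert_prior_set"` objects.
#' @export
read_prior_config <- function(path, tolerance = 1e-3) {
  cfg <- yaml::read_yaml(path)
  if (!length(cfg)) stop("prior config is empty: ", path, call. = FALSE)
  out <- lapply(names(cfg), function(id) {
    ivs <- lapply(cfg[[id]], function(e)
      elicited_interval(e$parameter, e$lower, e$upper, expert_id = id))
    build_expert_prior_set(ivs, expert_id = id, tolerance = tolerance)
  })
  stats::setNames(out, names(cfg))
}

#' Fitted-prior table across experts
#'
#' One row per expert with the fitted beta parameters (rounded to two
#' decimals for reporting; full precision is kept in the prior sets) and the
#' normal parameters of the log risk-ratio prior.
#'
#' @param prior_sets A list of `"expert_prior_set"` objects.
#' @return A data frame with columns `expert`, `p1_alpha`, `p1_beta`,
#'   `p0_alpha`, `p0_beta`, `log_rr_mu`, `log_rr_sigma`.
#' @export
prior_table <- function(prior_sets) {
  if (inherits(prior_sets, "expert_prior_set")) prior_sets <- list(prior_sets)
  do.call(rbind, lapply(prior_sets, function(ps) {
    data.frame(
      expert       = ps$expert_id,
      p1_alpha     = round(ps$p1_prior$alpha, 2),
      p1_beta      = round(ps$p1_prior$beta, 2),
      p0_alpha     = round(ps$p0_prior$alpha, 2),
      p0_beta      = round(ps$p0_prior$beta, 2),
      log_rr_mu    = round(ps$log_rr_prior$mu, 2),
      log_rr_sigma = round(ps$log_rr_prior$sigma, 2),
      row.names    = NULL
    )
  }))
}
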