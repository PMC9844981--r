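#' Bias parameters for a single binary unmeasured confounder
#'
#' A realized triple of bias parameters: the confounder prevalence among the
#' exposed (`p1`) and unexposed (`p0`) and the confounder-outcome risk ratio
#' (`rr_uy`).
#'
#' @param p1,p0 Proportions in \[0, 1\].
#' @param rr_uy Positive risk ratio.
#' @return An object of class `"bias_parameters"`.
#' @examples
#' bias_parameters(p1 = 0.3, p0 = 0.15, rr_uy = 2.35)
#' @export
bias_parameters <- function(p1, p0, rr_uy) {
  stopifnot(is.numeric(p1), is.numeric(p0), is.numeric(rr_uy))
  if (any(p1 < 0 | p1 > 1) || any(p0 < 0 | p0 > 1))
    stop("p1 and p0 must lie in [0, 1]", call. = FALSE)
  if (any(rr_uy <= 0))
    stop("rr_uy must be positive", call. = FALSE)
  structure(list(p1 = p1, p0 = p0, rr_uy = rr_uy), class = "bias_parameters")
}

#' Bias correction factor for a binary unmeasured confounder
#'
#' The multiplicative bias in the exposure-outcome risk ratio induced by a
#' binary confounder with prevalence `p1` among the exposed, `p0` among the
#' unexposed, and risk ratio `rr_uy` on the outcome:
#' \deqn{BCF = \frac{RR_{UY} P_1 + 1 - P_1}{RR_{UY} P_0 + 1 - P_0}.}
#' Dividing the measured-confounder-adjusted risk ratio by the BCF yields the
#' fully adjusted risk ratio.
#'
#' @param bp A [bias_parameters()] object (components may be vectors of equal
#'   length, in which case the factor is computed elementwise).
#' @return Positive numeric, the bias correction factor.
#' @examples
#' bias_correction_factor(bias_parameters(0.3, 0.15, 2.35))  # 1.17
#' @export
bias_correction_factor <- function(bp) {
  stopifnot(inherits(bp, "bias_parameters"))
  (bp$rr_uy * bp$p1 + 1 - bp$p1) / (bp$rr_uy * bp$p0 + 1 - bp$p0)
}

#' Bias-adjust a risk ratio for an unmeasured confounder
#'
#' @param unadjusted_rr Positive risk ratio adjusted for measured confounders
#'   only.
#' @param bp A [bias_parameters()] object.
#' @return An object of class `"correction_result"`: list with `bcf`,
#'   `unadjusted_rr`, `adjusted_rr` (`adjusted_rr * bcf == unadjusted_rr`).
#' @examples
#' adjust_rr(0.96, bias_parameters(0.3, 0.15, 2.35))  # adjusted 0.82
#' @export
adjust_rr <- function(unadjusted_rr, bp) {
  stopifnot(is.numeric(unadjusted_rr))
  if (any(unadjusted_rr <= 0))
    stop("unadjusted_rr must be positive", call. = FALSE)
  bcf <- bias_correction_factor(bp)
  structure(
    list(bcf = bcf, unadjusted_rr = unadjusted_rr,
         adjusted_rr = unadjusted_rr / bcf),
    class = "correction_result"
  )
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("unadjusted RR %.4g / BCF %.4g = adjusted RR %.4g\n",
              x$unadjusted_rr[1L], x$bcf[1L], x$adjusted_rr[1L]))
  invisible(x)
}

#' Typical bias-parameter values from elicited intervals
#'
#' The deterministic plug-in used to sanity-check the full analysis:
#' arithmetic means of the elicited interval endpoints for the two
#' prevalences and the geometric mean for the risk ratio.
#'
#' @param priors An `"expert_prior_set"` (which retains its source
#'   intervals).
#' @return A [bias_parameters()] object.
#' @examples
#' ps <- build_expert_prior_set(list(
#'   elicited_interval("P1", 0.20, 0.40),
#'   elicited_interval("P0", 0.10, 0.20),
#'   elicited_interval("RR_UY", 1.1, 5)
#' ))
#' typical_values(ps)  # p1 = 0.3, p0 = 0.15, rr_uy = 2.35
#' @export
typical_values <- function(priors) {
  stopifnot(inherits(priors, "expert_prior_set"))
  iv <- priors$intervals
  bias_parameters(
    p1    = (iv$P1$lower + iv$P1$upper) / 2,
    p0    = (iv$P0$lower + iv$P0$upper) / 2,
    rr_uy = sqrt(iv$RR_UY$lower * iv$RR_UY$upper)
  )
}

#' Draw bias parameters from an expert's fitted priors
#'
#' Independent draws of `(p1, p0, rr_uy)` from the two beta priors and the
#' log-normal risk-ratio prior. The three parameters are mutually independent;
#' no correlation structure is imposed.
#'
#' @param priors An `"expert_prior_set"`.
#' @param n Number of draws.
#' @return A [bias_parameters()] object with vector components of length `n`.
#' @export
draw_bias_parameters <- function(priors, n) {
  stopifnot(inherits(priors, "expert_prior_set"), n >= 1)
  bias_parameters(
    p1    = stats::rbeta(n, priors$p1_prior$alpha, priors$p1_prior$beta),
    p0    = stats::rbeta(n, priors$p0_prior$alpha, priors$p0_prior$beta),
    rr_uy = exp(stats::rnorm(n, priors$log_rr_prior$mu,
                             priors$log_rr_prior$sigma))
  )
}

#' Monte Carlo prior propagation of the bias correction
#'
#' Propagates prior uncertainty in the bias parameters through the correction
#' at a fixed unadjusted risk ratio: draws `(p1, p0, ln rr_uy)` independently
#' from the fitted priors, adjusts the risk ratio per draw, and summarises
#' the resulting distribution. Quantiles use the type-7 (linear
#' interpolation) convention.
#'
#' @param unadjusted_rr Positive risk ratio to be corrected.
#' @param priors An `"expert_prior_set"`.
#' @param n_draws Number of prior draws (at least 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `"posterior_summary"`: list with `draws`,
#'   `median`, `ci95` (2.5th/97.5th percentiles), `mcse` (batch-means Monte
#'   Carlo standard error of the mean), `n_draws`, and `expert_id`.
#' @examples
#' ps <- build_expert_prior_set(list(
#'   elicited_interval("P1", 0.20, 0.40),
#'   elicited_interval("P0", 0.10, 0.20),
#'   elicited_interval("RR_UY", 1.1, 5)
#' ))
#' monte_carlo_adjust(0.96, ps, n_draws = 10000, seed = 1)
#' @export
monte_carlo_adjust <- function(unadjusted_rr, priors, n_draws = 1e5,
                               seed = NULL) {
  stopifnot(is.numeric(unadjusted_rr), length(unadjusted_rr) == 1L,
            unadjusted_rr > 0)
  if (n_draws < 1000)
    stop("n_draws must be at least 1000 for stable percentile summaries",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  bp <- draw_bias_parameters(priors, n_draws)
  draws <- unadjusted_rr / bias_correction_factor(bp)
  posterior_summary(draws, expert_id = priors$expert_id)
}

#' Summarise a sample of adjusted risk ratios
#'
#' @param draws Numeric vector of adjusted-RR draws.
#' @param expert_id Optional label carried through to reports.
#' @param n_iter_used,converged MCMC bookkeeping (defaults for plain Monte
#'   Carlo samples).
#' @return An object of class `"posterior_summary"`.
#' @export
posterior_summary <- function(draws, expert_id = NULL,
                              n_iter_used = length(draws), converged = TRUE) {
  stopifnot(is.numeric(draws), length(draws) >= 4L)
  qs <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  structure(
    list(draws = draws, median = qs[2L], ci95 = c(qs[1L], qs[3L]),
         mcse = mcse(draws), n_draws = length(draws),
         n_iter_used = n_iter_used, converged = converged,
         expert_id = expert_id),
    class = "posterior_summary"
  )
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "adjusted RR %.3f (95%% interval %.3f-%.3f), %d draws, mcse %.2g%s%s\n",
    x$median, x$ci95[1L], x$ci95[2L], x$n_draws, x$mcse,
    if (!is.null(x$expert_id)) paste0(", ", x$expert_id) else "",
    if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}
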