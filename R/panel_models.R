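#' Default covariate columns for the panel outcome model
#'
#' Measured confounders entering the lagged outcome model: age (continuous,
#' centred by the fitter's design matrix only through its own column),
#' gender indicators with male as reference (the sparse transgender level is
#' retained as its own indicator), less-than-high-school education,
#' incarceration at baseline and in the recent interval, and ever having
#' been tested at baseline.
#'
#' @return Character vector of column names expected in the analysis records.
#' @export
panel_covariates <- function() {
  c("age", "gender_female", "gender_transgender", "education_lths",
    "incarcerated_baseline", "incarcerated_recent", "ever_tested_baseline")
}

# Expand the raw gender factor into the indicator columns the models use.
.expand_gender <- function(df) {
  if ("gender" %in% names(df) && !"gender_female" %in% names(df)) {
    df$gender_female      <- as.integer(df$gender == "female")
    df$gender_transgender <- as.integer(df$gender == "transgender")
  }
  df
}

#' Build lagged, censored analysis records from visit rows
#'
#' Pairs consecutive visits within subject: the exposure is unsafe injection
#' reported at visit `t`, the outcome is not-being-tested (NBT) at visit
#' `t + 1`. Subjects are censored at their first HIV-positive visit: no pair
#' uses data at or after that visit. Covariates are taken at the exposure
#' visit. Rows with missing exposure or outcome are dropped listwise and the
#' count reported via `message()`.
#'
#' @param visits Data frame with one row per visit: columns `subject_id`,
#'   `visit_index` (strictly increasing within subject), `unsafe_injection`,
#'   `nbt`, `hiv_positive`, plus covariate columns (either a `gender` factor
#'   or the expanded indicators) as listed by [panel_covariates()].
#' @return A data frame of analysis records with columns `subject_id`,
#'   `exposure` (unsafe injection at `t`), `outcome` (NBT at `t + 1`) and the
#'   covariates, one row per usable consecutive visit pair.
#' @export
build_analysis_records <- function(visits) {
  stopifnot(is.data.frame(visits))
  need <- c("subject_id", "visit_index", "unsafe_injection", "nbt",
            "hiv_positive")
  miss <- setdiff(need, names(visits))
  if (length(miss))
    stop("visits is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  visits <- .expand_gender(visits)
  covs <- intersect(panel_covariates(), names(visits))

  pieces <- lapply(split(visits, visits$subject_id), function(v) {
    vi <- v$visit_index
    if (anyDuplicated(vi))
      stop("duplicated visit_index within subject ", v$subject_id[1L],
           call. = FALSE)
    if (is.unsorted(vi, strictly = TRUE))
      stop("visit_index not strictly increasing within subject ",
           v$subject_id[1L], call. = FALSE)
    # censor at the first HIV-positive visit: that visit and everything after
    # contribute nothing, to either exposures or outcomes
    pos <- which(v$hiv_positive == 1L)
    if (length(pos)) v <- v[seq_len(pos[1L] - 1L), , drop = FALSE]
    n <- nrow(v)
    if (n < 2L) return(NULL)
    idx <- seq_len(n - 1L)
    rec <- data.frame(subject_id = v$subject_id[idx],
                      exposure   = v$unsafe_injection[idx],
                      outcome    = v$nbt[idx + 1L])
    for (cn in covs) rec[[cn]] <- v[[cn]][idx]
    rec
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- stats::setNames(
      as.data.frame(matrix(nrow = 0L, ncol = 3L + length(covs))),
      c("subject_id", "exposure", "outcome", covs))
  rownames(out) <- NULL
  keep <- !(is.na(out$exposure) | is.na(out$outcome))
  if (any(!keep))
    message("dropped ", sum(!keep),
            " record(s) with missing exposure or outcome")
  out[keep, , drop = FALSE]
}

# Design matrix (intercept, exposure, covariates) and response for the
# panel fitters; clusters are subjects in record order of first appearance.
.panel_design <- function(records, covariates, min_clusters = 2L) {
  covariates <- intersect(covariates, names(records))
  cluster <- match(records$subject_id, unique(records$subject_id))
  if (max(cluster) < min_clusters)
    stop("need at least ", min_clusters, " clusters (subjects)",
         call. = FALSE)
  # a covariate level absent from these records (e.g. no transgender
  # subjects in a small cohort) yields a constant column a factor design
  # would never have created; drop it rather than fail
  constant <- vapply(covariates, function(cn)
    length(unique(records[[cn]])) < 2L, logical(1L))
  if (any(constant)) {
    message("dropping constant covariate column(s): ",
            paste(covariates[constant], collapse = ", "))
    covariates <- covariates[!constant]
  }
  X <- cbind(`(Intercept)` = 1, exposure = as.numeric(records$exposure))
  for (cn in covariates) X <- cbind(X, as.numeric(records[[cn]]))
  colnames(X) <- c("(Intercept)", "exposure", covariates)
  # rank check on column-normalised Gram matrix: stable for near-empty
  # indicator columns and invariant to record ordering
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0))
    stop("design matrix is rank deficient; drop collinear covariates",
         call. = FALSE)
  ev <- eigen(crossprod(X / rep(nrm, each = nrow(X))), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) / max(ev) < 1e-12)
    stop("design matrix is rank deficient; drop collinear covariates",
         call. = FALSE)
  list(X = X, y = as.numeric(records$outcome), cluster = cluster)
}

# Solve H x = u with Jacobi preconditioning: near-empty covariate levels
# make H badly scaled even when the design has full rank.
.precond_solve <- function(H, u) {
  s <- sqrt(diag(H))
  if (is.matrix(u)) drop(solve(H / tcrossprod(s), u / s) / s)
  else solve(H / tcrossprod(s), u / s) / s
}
.precond_inverse <- function(H) {
  s <- sqrt(diag(H))
  solve(H / tcrossprod(s)) / tcrossprod(s)
}

#' GEE Poisson regression with a log link and cluster-robust variance
#'
#' Marginal ("modified Poisson") regression of a binary outcome on the
#' lagged exposure and measured confounders, targeting the risk ratio
#' directly. Solves the GEE score equations by Fisher scoring under an
#' exchangeable (default) or independence working correlation, with the
#' exchangeable inverse computed in closed form, and estimates the variance
#' by the cluster-robust sandwich.
#'
#' @param records Analysis records from [build_analysis_records()].
#' @param covariates Covariate columns to adjust for (default
#'   [panel_covariates()]; only those present in `records` are used).
#' @param working_correlation `"exchangeable"` or `"independence"`.
#' @param max_iter,tol Fisher-scoring iteration cap and convergence tolerance
#'   on the coefficient change.
#' @return An object of class `"frequentist_fit"`: coefficients on the
#'   log-RR scale, robust covariance, `exposure_rr` with Wald `ci95`,
#'   working-correlation estimate `alpha`, dispersion `phi`, `n_subjects`,
#'   `n_records`.
#' @export
fit_gee_poisson <- function(records, covariates = panel_covariates(),
                            working_correlation = c("exchangeable",
                                                    "independence"),
                            max_iter = 50L, tol = 1e-10) {
  working_correlation <- match.arg(working_correlation)
  d <- .panel_design(records, covariates)
  X <- d$X; y <- d$y; cl <- d$cluster
  n_cl <- max(cl)
  p <- ncol(X)
  idx <- split(seq_along(y), cl)

  beta <- stats::glm.fit(X, y, family = stats::poisson())$coefficients
  alpha <- 0
  for (it in seq_len(max_iter)) {
    mu <- exp(drop(X %*% beta))
    if (any(!is.finite(mu)) || any(mu > 1e8))
      stop("GEE diverged (unbounded fitted means); check for separation",
           call. = FALSE)
    r <- (y - mu) / sqrt(mu)
    phi <- sum(r^2) / (length(y) - p)
    if (working_correlation == "exchangeable") {
      num <- 0; npairs <- 0
      for (ix in idx) {
        ni <- length(ix)
        if (ni > 1L) {
          num <- num + (sum(r[ix])^2 - sum(r[ix]^2)) / 2
          npairs <- npairs + ni * (ni - 1) / 2
        }
      }
      alpha <- if (npairs > p) num / ((npairs - p) * phi) else 0
      alpha <- min(max(alpha, 0), 0.95)
    }
    H <- matrix(0, p, p); U <- numeric(p); B <- matrix(0, p, p)
    for (ix in idx) {
      ni <- length(ix)
      Ai <- sqrt(mu[ix])
      Di <- X[ix, , drop = FALSE] * mu[ix]            # d mu / d beta
      # V^{-1} = A^{-1/2} R^{-1} A^{-1/2} / phi, with exchangeable
      # R^{-1} = [I - alpha/(1 + (ni-1) alpha) J] / (1 - alpha)
      Zi <- Di / Ai                                    # A^{-1/2} D
      si <- (y[ix] - mu[ix]) / Ai                      # A^{-1/2} residual
      if (alpha > 0 && ni > 1L) {
        c1 <- 1 / (1 - alpha)
        c2 <- alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
        RiZ <- c1 * Zi - c2 * matrix(colSums(Zi), ni, p, byrow = TRUE)
        Ris <- c1 * si - c2 * sum(si)
      } else {
        RiZ <- Zi; Ris <- si
      }
      H <- H + crossprod(Zi, RiZ) / phi
      ui <- crossprod(RiZ, si) / phi
      U <- U + ui
      B <- B + tcrossprod(ui)
    }
    step <- .precond_solve(H, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  Hi <- .precond_inverse(H)
  vcov <- Hi %*% B %*% Hi
  vcov <- (vcov + t(vcov)) / 2
  se <- sqrt(diag(vcov))
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(
    list(coefficients = beta, robust_covariance = vcov,
         exposure_rr = exp(beta[["exposure"]]),
         ci95 = exp(beta[["exposure"]] + c(-1.96, 1.96) * se[2L]),
         exposure_se_log = se[2L],
         alpha = alpha, phi = phi,
         working_correlation = working_correlation,
         n_subjects = n_cl, n_records = length(y),
         converged = max(abs(step)) < tol, method = "gee_poisson"),
    class = "frequentist_fit"
  )
}

#' Random-intercept Poisson regression by maximum likelihood
#'
#' The conditional counterpart of [fit_gee_poisson()]: a log-link Poisson
#' model with a Gaussian per-subject intercept, fitted by adaptive
#' Gauss-Hermite quadrature via [lme4::glmer()]. Because the risk ratio is
#' collapsible over an independent random intercept on the log scale, its
#' conditional exposure RR should agree with the marginal GEE estimate.
#'
#' @inheritParams fit_gee_poisson
#' @param nAGQ Number of adaptive quadrature points.
#' @return A `"frequentist_fit"` with the conditional exposure RR, Wald CI
#'   and the estimated random-intercept standard deviation `re_sd`.
#' @export
fit_re_poisson_ml <- function(records, covariates = panel_covariates(),
                              nAGQ = 9L) {
  d <- .panel_design(records, covariates)  # validates rank
  covariates <- intersect(covariates, names(records))
  df <- records
  df$.subject <- factor(df$subject_id)
  rhs <- paste(c("exposure", covariates, "(1 | .subject)"), collapse = " + ")
  fit <- lme4::glmer(stats::as.formula(paste("outcome ~", rhs)),
                     data = df, family = stats::poisson(), nAGQ = nAGQ,
                     control = lme4::glmerControl(
                       check.conv.singular = "ignore",
                       calc.derivs = FALSE))
  beta <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(vc))
  k <- match("exposure", names(beta))
  structure(
    list(coefficients = beta, robust_covariance = vc,
         exposure_rr = exp(beta[[k]]),
         ci95 = exp(beta[[k]] + c(-1.96, 1.96) * se[k]),
         exposure_se_log = se[k],
         re_sd = sqrt(unname(lme4::VarCorr(fit)$.subject[1L])),
         n_subjects = length(unique(records$subject_id)),
         n_records = nrow(records),
         converged = length(fit@optinfo$conv$lme4) == 0L,
         method = "re_poisson_ml", model = fit),
    class = "frequentist_fit"
  )
}

#' @export
print.frequentist_fit <- function(x, ...) {
  cat(sprintf(
    "%s: exposure RR %.3f (95%% CI %.3f-%.3f), %d subjects, %d records\n",
    x$method, x$exposure_rr, x$ci95[1L], x$ci95[2L],
    x$n_subjects, x$n_records))
  invisible(x)
}
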