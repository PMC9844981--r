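---
title: "Bayesian bias analysis for an unmeasured confounder: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian bias analysis for an unmeasured confounder: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biasbayes)
```

## The problem

Observational panel studies of persons who inject drugs (PWID) can estimate
the association between unsafe injection (sharing, reusing or borrowing
drug-preparation equipment) and not being tested (NBT) for HIV in the
following interval, adjusted for whatever was measured — age, gender,
education, incarceration, prior testing. What they cannot adjust for is what
was never collected. Insufficient knowledge of HIV transmission routes is a
textbook candidate: it plausibly raises the probability of unsafe injection
*and* the probability of skipping an HIV test, so the conventional estimate
confounds the two pathways.

`biasbayes` implements a probabilistic (Bayesian) bias analysis for exactly
this situation: a single binary unmeasured confounder $U$ acting on a binary
exposure $E$ and binary outcome $D$ on the risk-ratio scale, in a
longitudinal cohort with one-visit exposure lag.

## Bias parameters and the correction factor

Three bias parameters describe the confounder:

* $P_1 = \Pr(U = 1 \mid E = 1)$, its prevalence among the exposed,
* $P_0 = \Pr(U = 1 \mid E = 0)$, its prevalence among the unexposed,
* $RR_{UY}$, the risk ratio of $U$ on the outcome.

Under the standard assumptions for external adjustment (a single binary
confounder whose effect on the outcome is the same in both exposure groups,
no effect modification on the ratio scale), the confounder multiplies the
exposure–outcome risk ratio by the bias correction factor

$$
\mathrm{BCF} \;=\; \frac{RR_{UY}\,P_1 + 1 - P_1}{RR_{UY}\,P_0 + 1 - P_0},
$$

so the fully adjusted risk ratio is the measured-confounder-adjusted risk
ratio divided by the BCF. `bias_correction_factor()` and `adjust_rr()` are
direct implementations; both are exercised against hand arithmetic in the
test suite (for instance $P_1 = 0.3$, $P_0 = 0.15$, $RR_{UY} = 2.35$ gives
$\mathrm{BCF} = 1.17$ and $0.96 / 1.17 = 0.82$).

The formula treats $RR_{UY}$ as common to both exposure strata. The
elicitation materials are ambiguous about which stratum the experts were
asked about; the package stores a single $RR_{UY}$ per expert and does not
attempt to resolve the ambiguity.

## Eliciting priors from expert intervals

Experts state 95% intervals, not distributions. The package converts them:

* **Proportions** ($P_1$, $P_0$): a beta distribution whose 2.5th and
  97.5th percentiles match the stated interval. `fit_beta_from_interval()`
  minimises the summed squared percentile error over $(\log\alpha,
  \log\beta)$, seeding a Nelder–Mead refinement from a deterministic
  log-spaced grid of 60 effective sample sizes $\alpha+\beta \in [0.5,
  5000]$ with the beta mean anchored at the interval midpoint. The fit must
  reproduce each percentile within `tolerance` (default $10^{-3}$ on the
  probability scale) or it fails loudly. The achieved percentile error at
  the published intervals is far below the tolerance, and the fitted
  percentiles are cross-checked in the tests against an independent
  numerical-integration CDF oracle to $10^{-6}$.
* **Risk ratio** ($RR_{UY}$): a normal prior for $\ln RR_{UY}$ with
  $\mu = (\ln l + \ln u)/2$ and $\sigma = (\ln u - \ln l)/3.92$. Because
  $3.92 = 2 \times 1.96$, $\exp(\mu \pm 1.96\sigma)$ recovers the elicited
  bounds exactly; this moment rule is used as stated rather than refitted
  by quantile matching.

Each expert's three fitted priors form an `expert_prior_set`, which also
retains the raw intervals: the deterministic "typical values" plug-in
(arithmetic means of the proportion limits, geometric mean of the
risk-ratio limits) is defined on interval endpoints, not on the fitted
distributions. Experts are analysed separately throughout; pooling
elicitations into a consensus prior is deliberately out of scope because no
principled pooling rule was part of the elicitation design.

## Conventional analysis

`build_analysis_records()` pairs consecutive visits within subject:
exposure at visit $t$, outcome at visit $t+1$, covariates at $t$. Subjects
are censored at their first HIV-positive visit — no pair may use data at or
after it — and rows with missing exposure or outcome are dropped listwise
with a reported count.

`fit_gee_poisson()` estimates the marginal exposure risk ratio by solving
the GEE score equations for a log-link Poisson working model ("modified
Poisson" regression — the standard way to target a risk ratio for a common
binary outcome, where log-binomial fits routinely fail to converge), with a
cluster-robust sandwich variance. The working correlation defaults to
exchangeable, whose inverse is applied in closed form; independence is
available and is the configuration cross-checked against
`glm(family = poisson)` plus `sandwich::vcovCL()` in the tests. Two
numerical choices matter in small cohorts: covariate columns that are
constant in the analysis records (e.g. an absent transgender level) are
dropped, as a factor-based design matrix would never have created them, and
the Fisher-scoring solves are Jacobi-preconditioned because a level carried
by a handful of records makes the information matrix badly scaled long
before it is genuinely singular.

`fit_re_poisson_ml()` is the conditional counterpart — a Gaussian
random-intercept Poisson model fitted by adaptive Gauss–Hermite quadrature
(`lme4::glmer`, 9 points by default). Because the risk ratio is collapsible
over an independent random intercept on the log scale, the conditional and
marginal estimates should agree; this agreement is asserted on large
synthetic cohorts in the acceptance tests.

## The Bayesian bias analysis

The Bayesian model is the random-intercept Poisson model with diffuse
priors: $N(0, 10^6)$ on every regression coefficient and a
$\mathrm{Gamma}(0.001, 0.001)$ prior on the precision $1/\tau$ of the
random intercepts. The sampler (in compiled code) is
Metropolis-within-Gibbs:

* componentwise random-walk Metropolis for the coefficients,
* one joint vector of random-walk updates for the subject intercepts
  (each accepted or rejected independently given the others), and
* a conjugate Gibbs draw for the precision,
  $1/\tau \mid b \sim \mathrm{Gamma}(0.001 + n/2,\; 0.001 + \sum_i b_i^2/2)$.

Step sizes adapt toward a 0.44 acceptance rate in 50-iteration blocks
*during burn-in only* and are frozen afterwards, so the post-burn-in kernel
satisfies detailed balance. The tests verify the precision step against its
analytic full conditional by Kolmogorov–Smirnov test with the other updates
frozen. Chains start at the Poisson GLM estimate; all randomness flows
through R's RNG, so runs are exactly reproducible under a seed.

Per retained iteration the three bias parameters are drawn from the
expert's fitted priors — mutually independently, and independently of the
data, since nothing in the likelihood identifies them — and the iteration's
bias-adjusted risk ratio is $\exp(\beta_E)/\mathrm{BCF}$. The *conditional*
exposure coefficient is used; by collapsibility this matches the marginal
choice here, and the tests confirm the unadjusted posterior median tracks
the GEE estimate.

The default schedule mirrors the analysis protocol: 1000 burn-in
iterations, an initial run of 4000 total, then extension in blocks of 2000
until the batch-means Monte Carlo standard error of the adjusted RR falls
below 5% of its posterior SD, capped at 10 000 total iterations. No
thinning is applied; the batch-means MCSE (batch size $\lfloor\sqrt
n\rfloor$) accounts for autocorrelation. Posterior summaries are the
median and the 2.5th/97.5th percentiles, using the type-7 (linear
interpolation) quantile convention.

`monte_carlo_adjust()` is the model-free special case — prior draws applied
to a fixed unadjusted RR — and doubles as a validation target: running the
full machinery with a degenerate exposure posterior must reproduce its
output distribution (checked by KS test).

## The synthetic cohort generator

No deposited microdata exist for the motivating cohort, so
`simulate_cohort()` generates study-like data with a *known* confounder,
making every downstream stage testable against ground truth:

* **Cohort frame.** 601 subjects. Visit counts are $2 +
  \mathrm{NB}(\text{size}=0.1,\ \mu = 2.3)$: every subject has a baseline
  and at least one follow-up visit (the cohort's inclusion rule), the mean
  is 4.3, and the small size parameter reproduces the heavy upper tail
  implied by a published SD (7.7) far above the mean. The count family is a
  declared assumption; only the mean and dispersion were published.
* **Covariates.** Drawn from the published baseline composition (gender
  65/34/1% male/female/transgender, 39% less than high school, 28% ever
  incarcerated, 29% ever tested; age $N(23.6, 3.4^2)$), which the package
  recomputes from the printed summary counts via `baseline_composition()`.
  Covariate effects on the outcome default to zero so that confounding runs
  only through $U$ and clustering only through the random intercept; both
  are configurable.
* **Exposure.** A two-state Markov chain with baseline prevalence 0.659
  and persistence 0.8, the entry probability solved so the chain is
  stationary at the baseline prevalence.
* **Confounder.** $U$ is redrawn each visit with probability $p_1$ given
  current exposure, $p_0$ otherwise — the simplest reading of a
  time-varying confounder. Exposure–confounder feedback exists as a switch
  (`u_feedback`) but is off by default; handling feedback properly needs
  g-methods, which are out of scope.
* **Outcome.** $\Pr(D_{t+1} = 1) = \pi_0 \cdot
  RR_E^{E_t} \cdot RR_{UY}^{U_t} \cdot e^{x'\gamma + b_i}$ with
  $b_i \sim N(0, \sigma_b^2)$, truncated at 1 with truncation counted.
  Defaults: $\pi_0 = 0.2$, $RR_E = 0.822$, $(p_1, p_0, RR_{UY}) = (0.30,
  0.15, 2.35)$ — the typical values of the stronger expert — so the
  $U$-blind marginal risk ratio sits near $0.822 \times 1.17 \approx 0.96$,
  and $\sigma_b = 0.25$. The baseline risk and intercept SD are bounded
  above by coherence of the log-link model itself: with $RR_{UY} = 2.35$, a
  baseline much above 0.2 pushes model-implied risks past 1. Construction
  fails if the worst typical-case risk is materially above 1, and
  generation fails if the realized truncation rate is statistically
  incompatible with 0.1% (a plain threshold would trip on one or two tail
  events in small cohorts).
* **Censoring.** HIV seroconversion is an absorbing per-visit event
  (default probability 0.01) that the analysis stage censors at.

`empirical_bias_check()` uses the withheld $U$ to report realized
$(p_1, p_0, RR_{UY})$, the crude and $U$-adjusted risk ratios, and the
realized correction factor; the tests assert that the crude/adjusted gap
converges to the closed-form BCF as the cohort grows — the self-consistency
between the generator's causal structure and the correction formula.

## What the passing tests do and do not show

The generator draws time-fixed covariates independently, gives every
subject the same visit process, and makes missingness essentially absent;
real cohorts have informative follow-up, correlated covariates, recall and
social-desirability error in self-reports, and possibly several correlated
unmeasured confounders. Passing the recovery tests therefore shows the
*machinery* is correct under the stated causal structure, not that the
bias-adjusted estimate is right for any particular real cohort — with
non-identified bias parameters, the answer is only ever as good as the
elicited priors. Notable limitations found and quantified during
validation:

* **Poisson working likelihood on binary outcomes.** The Bernoulli
  conditional variance $\mu(1-\mu)$ is smaller than the Poisson's $\mu$, so
  the random-intercept variance is pushed to the zero boundary on binary
  panels at these event rates (the heterogeneity signal is smaller than the
  underdispersion deficit), and posterior spread for the exposure
  coefficient is mildly conservative. Point estimation is unaffected —
  this is the same trade accepted by modified Poisson regression. The
  variance-recovery test therefore uses genuine Poisson counts.
* **Second-order small-sample bias.** At 200 subjects the log-RR estimate
  carries a bias of roughly $+0.01$ (measured over 1000 replicates,
  decaying with $n$), ordinary for ratio estimators at this size.
* **Prior-propagation medians.** The median of $0.96/\mathrm{BCF}$ under
  independent prior draws differs slightly from $0.96$ divided by the BCF
  at componentwise typical values (0.83 vs 0.82 under the wider expert's
  priors), because the BCF distribution is skewed and its numerator and
  denominator share the $RR_{UY}$ draw. Both quantities are computed by
  the package; the worked-example arithmetic matches the plug-in exactly.

## Problem sizes used by the test suite

Deterministic checks run at the published values. Stochastic checks use:
500-draw to $10^5$-draw Monte Carlo summaries; GEE coverage over 300
replicates of 200-subject cohorts; parameter recovery over 200 replicates
of 200-subject cohorts with 2000 MCMC iterations each; cross-method and
distributional (KS) checks on single cohorts of 1200–1500 subjects. These
sizes are the package's own validation design and are stated here so the
reported Monte Carlo tolerances can be interpreted.
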