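---
title: "Residential isolation and late-stage diagnosis: models and methods"
author: "isostage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residential isolation and late-stage diagnosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isostage)
```

## The scientific problem

Roughly a third of U.S. breast cancers are first diagnosed at a late
(regional or distant) stage, and the odds of late-stage diagnosis differ
across racial/ethnic groups and across places. One line of health-outcomes
research asks whether *residential segregation* — specifically the
exposure-dimension Isolation Index — helps explain those differences, and,
importantly, whether the answer depends on how segregation is attached to
people:

* **place-centered**: every resident of a county carries every group's
  county Isolation Index, so a coefficient measures what it means to live
  in, say, a highly isolated White county, whatever the resident's own
  group;
* **person-centered**: each person carries only their own group's index,
  a single "race-matched" exposure.

`isostage` packages that comparison as a reusable pipeline: index
construction, registry-style cohort assembly, a three-level random
intercept logistic model, and county-level residual diagnostics — all
exercisable on synthetic data with known truth, since real registry files
with county of residence are access-restricted.

## The Isolation Index

For county $j$ with tracts $i = 1, \dots, N$, group count $x_i$, tract
total $t_i$ and county group total $X = \sum_i x_i$,

$$I_j = \sum_{i=1}^{N} \frac{x_i}{X}\,\frac{x_i}{t_i} \in [0, 1],$$

the probability that a group member's random within-county contact belongs
to the same group. Three conventions matter in practice and are fixed
here:

* $X = 0$ (group absent from the county) leaves the index **missing**,
  not zero — zero would assert "no isolation", which the formula does not
  support. Downstream code treats missingness explicitly (complete-case
  modelling, averaging over available indices for the residual "Other"
  group).
* Tracts with zero population and zero counts contribute nothing and are
  dropped from the sum; a positive count in a zero-population tract is a
  validation error.
* A county where every tract has the same group share $p$ has $I_j = p$
  exactly; full concentration of the group into its own tracts drives
  $I_j$ to 1. Both identities are enforced in the test suite against a
  naive double-loop evaluation of the sum.

A county is flagged *hyper-segregated* for a group when $I_j \ge 0.90$
(boundary inclusive); the threshold is a parameter.

## Cohort construction

Records are excluded when the case is not the person's primary cancer,
when the stage is unknown/unstaged, or when diagnosis came from autopsy or
a death certificate. A record matching several rules is tallied once under
the first matching reason, in the order non-primary → unknown stage →
autopsy/death certificate; the order is configurable because registry
reports list the shares separately without defining a precedence. Retained
plus tallied counts always equal the input count.

Exposure attachment follows the two constructions above. For the residual
"Other" race/ethnicity group, which has no index of its own, the
person-centered exposure is the unweighted mean of the county's
non-missing group indices; the contributing set is configurable since
reasonable analysts may include or exclude the smallest groups.

## The three-level model

With persons $i$ nested in counties $j$ nested in states $k$,

$$\operatorname{logit} P(y_{ijk} = 1) = x_{ijk}'\beta + u_{jk} + v_k,
\qquad u_{jk} \sim N(0, \sigma^2_{county}), \quad
v_k \sim N(0, \sigma^2_{state}).$$

The marginal likelihood factorises over states; inside a state the county
integrals are conditionally independent given $v_k$. `isostage` evaluates
the likelihood by **nested adaptive Gauss–Hermite quadrature** (AGQ): the
state integral uses quadrature nodes centred at the posterior mode of
$v_k$ with a curvature-matched scale, and at each state node every county
integral uses nodes centred at that county's conditional posterior mode.
`quad_points = 7` nodes per level is the default; with one node the scheme
reduces to a nested Laplace approximation. Estimates at 7 and 15 nodes
agree to well under $10^{-3}$ on the standard synthetic fixture, and the
whole fit is cross-checked in the test suite against an independent
implementation (`lme4::glmer` with nested random intercepts) and, with the
variances constrained to zero, against single-level IRLS (`stats::glm`).

Numerical choices:

* Variances are optimised as log standard deviations (non-negativity by
  construction), with BFGS on the marginal deviance. The fixed effects
  start at the single-level `glm` solution; the log-SDs start at
  $\log 0.05$.
* The gradient is computed analytically inside the quadrature as the
  posterior-mean score (adaptation points held fixed, the standard AGQ
  approximation); the observed information for standard errors comes from
  central finite differences of that gradient at the optimum. Wald
  confidence intervals are symmetric on the log-odds scale and
  exponentiated, and p-values are two-sided Wald.
* Convergence is declared when the relative change in the log-likelihood
  between accepted iterations falls below `tol`. The default is
  `1e-8`: at cohort sizes in the tens of thousands the log-likelihood is
  of order $10^4$, and a looser relative threshold can stop the optimizer
  while a weakly identified coefficient is still moving (we observed a
  0.15 log-odds gap against the verified optimum under a $10^{-6}$
  threshold). Non-convergence is returned explicitly
  (`converged = FALSE`, with a warning), never silently.
* Clusters whose outcomes are all 0 or all 1 are retained — the marginal
  likelihood handles them — but complete separation in the fixed effects
  aborts with a diagnostic, since no finite MLE exists.
* A variance estimate that collapses below $10^{-16}$ is reported as
  exactly zero and its parameter is excluded from the differenced
  information block (its gradient is flat).

On the latent-response scale the person-level residual of a logistic
model has the fixed variance $\pi^2/3 \approx 3.2899$; it is a constant of
the model, reported but never estimated. Intraclass correlations are
latent-scale variance shares,
$\mathrm{ICC}_{state} = \sigma^2_{state} / D$ and
$\mathrm{ICC}_{county} = (\sigma^2_{state} + \sigma^2_{county}) / D$ with
$D = \sigma^2_{state} + \sigma^2_{county} + \pi^2/3$.

Empirical-Bayes intercepts are posterior modes given the estimated
parameters: the state mode is found with the counties integrated out, and
county modes are then computed conditional on the state modes. Predictions
are the inverse-logit of the linear predictor, optionally adding these
modes; clusters unseen at fit time contribute zero (logged).

## County-level residual diagnostics

Per county the package reports the observed late-stage proportion, the
mean predicted probability (random intercepts included), and their
difference, **always observed minus predicted**. Counties whose difference
lies at least $k$ population standard deviations from the mean difference
(default $k = 2$, both tails, boundary inclusive) are flagged as
outliers. The population SD (denominator $n$) is used so that the flagging
rule has the exact closed-form behaviour documented in the tests — e.g.
differences $\{0,0,0,0,0.5\}$ have mean $0.1$ and SD $0.2$, so at $k = 2$
exactly the $0.5$ county sits on the threshold and is flagged.

Spatial structure in the differences is tested with global Moran's I,

$$I = \frac{n}{S_0}\,
\frac{\sum_{ij} w_{ij} (z_i - \bar z)(z_j - \bar z)}
     {\sum_i (z_i - \bar z)^2},$$

whose permutation expectation is $-1/(n-1)$: $-1$ indicates perfect
dispersion, values near the expectation spatial randomness, $+1$ perfect
clustering. Because no canonical weight matrix exists for this diagnostic,
the package defaults to queen contiguity when an adjacency list is
supplied and otherwise to $k = 5$ nearest neighbours by county centroid,
row-standardized; the scheme is recorded in every Moran report.
Significance uses a two-sided permutation test,
$p = (1 + \#\{|I_{perm}| \ge |I_{obs}|\}) / (1 + n_{perm})$ with 999
permutations and an explicit seed. Permutation p-values are valid for any
statistic under exchangeability, and the test suite confirms 5% ± 2%
rejection under iid noise on a fixed lattice, exactness of $-1$ on a
checkerboard, and agreement with both a textbook triple-loop
implementation and `ape::Moran.I`.

## The synthetic cohort generator

The generator is the package's study-condition definition, not a tuning
knob. Geography: county group mixes are Dirichlet draws centred on a
national baseline (White/Black/Hispanic/Asian roughly 78/10/8/3 percent,
the registry composition); tract mixes are Dirichlet draws centred on the
county mix with total concentration `segregation_alpha`, the single
segregation dial — small values push tracts toward single-group
composition, `alpha` $\to \infty$ recovers the even-distribution identity
$I_j = p$. Tract counts are multinomial given Poisson tract totals (mean
4000, a typical census-tract size). Defaults: 10 states × 20
counties × 10 tracts, 250 cases per county (50,000 cases),
`county_concentration = 5` (wide between-county heterogeneity, as in U.S.
counties), `segregation_alpha = 0.5` (strongly segregated tracts, so
White isolation indices reach the high values seen in county data).

Cases draw race from their county's realized composition plus a 1.3%
residual "Other" share, age from the registry age distribution
(22.6/36.6/21.9/18.9 percent for <50, 50–64, 65–74, 75+), and independent
exclusion flags at 2%, 2.5% and 1%. Outcomes come from the three-level
logistic truth model; default log-odds mirror large-registry magnitudes
(Black OR 1.45, Hispanic 1.253, Asian 0.974, Other 0.88; age <50 1.342,
50–64 1.063, 65–74 0.894; intercept $\operatorname{logit}(0.30)$ so the
overall prevalence is near the observed 0.308), with
$\sigma^2_{county} = 0.0103$ and $\sigma^2_{state} = 0.0037$. Random-number
streams are split per stage, so enlarging the cohort never perturbs the
geography.

What the generator does **not** emulate: real U.S. geography and
census calibration, spatially autocorrelated random effects, residential
history, within-county tract assignment of persons, or correlation between
county composition and county-level care covariates. Passing tests
therefore demonstrate correctness of the machinery and recoverability of
parameters under the stated model, not robustness to the ways real
registry data violate it.

## Validation strategy and problem sizes

The test suite checks every closed-form example by direct arithmetic,
every stochastic claim under fixed seeds, and the full pipeline by
parameter recovery: 50 replicates of the default 50,000-case
configuration, asserting that the mean recovered Black log-odds sits
within 3 Monte-Carlo standard errors of $\log 1.45$, that per-term bias is
within 3 Monte-Carlo SEs, and that 95% Wald intervals cover the truth in
at least 88% of replicates. Smaller fixtures (4 states × 5 counties,
60–250 cases per county, `county_concentration = 50` so every race level
is represented) are used for unit-level checks where the full size adds
nothing. `scripts/acceptance.R` re-runs the main computations from scratch
at the default study size and writes a JSON report.

## Known limitations

* The fitter supports exactly the model class used here: nested random
  intercepts, logit link. No random slopes, crossed effects, survey
  weights or alternative links.
* Wald inference for variance components is not reported; with 10 states
  the state-level variance is weakly identified and ML estimates can sit
  at the zero boundary.
* The Moran diagnostic tests the county differences as given; it does not
  re-estimate the model spatially.
* With heavily segregated small geographies a group can be absent from
  every tract of a county; its index is missing there by design, and
  person-centered complete-case modelling will drop the affected
  residents (counted in the build log).
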