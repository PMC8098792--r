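---
title: "Multi-way additive interaction: models, measures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-way additive interaction: models, measures, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rerin)
```

## The scientific problem

Two risk factors interact *on the additive scale* when the excess risk of
their joint presence differs from the sum of their individual excess risks.
Additive interaction is the public-health-relevant notion: it answers
whether the caseload attributable to two exposures acting together exceeds
what each would contribute on its own.  The classical measure is the
relative excess risk due to interaction,

$$\mathrm{RERI}_2 = RR_{11} - RR_{10} - RR_{01} + 1,$$

positive for super-additive, zero for additive, negative for sub-additive
joint effects.  `rerin` extends this machinery to any number $n$ of binary
risk factors.

## Measures

Write $RR_p$ for the relative risk of exposure pattern
$p \in \{0,1\}^n$, referenced to the all-absent pattern ($RR_{0\cdots0} = 1$),
and $\mathrm{ERR}_p = RR_p - 1$ for the excess relative risk.  The package
implements:

* **Total RERI** — the joint departure from additivity of all $n$ factors:
  $\mathrm{TotRERI}_n = RR_{1\cdots1} - \sum_i RR_{e_i} + (n-1)$, where
  $e_i$ is the pattern with only factor $i$ present.  It aggregates the
  $n$-way interaction *and* every lower-order interaction.
* **Top-order RERI** — the $n$-way interaction net of all lower orders, the
  alternating inclusion–exclusion sum
  $\mathrm{RERI}_n = \sum_{p} (-1)^{\,n - |p|} RR_p$ over all $2^n$
  patterns ($|p|$ = number of present factors).
* **Conditional lower-order RERIs** — the RERI of a subset $S$ within a
  stratum $z$ of the remaining factors.  When a conditioning factor is
  present, all RRs are re-referenced by dividing by the stratum baseline
  $RR_{S\,\text{absent},\,z}$; with $z$ all-absent this reduces to the plain
  lower-order RERI.
* **Decomposition** — the exact identity
  $\mathrm{TotRERI}_n = \mathrm{RERI}_n + \sum_{2 \le |S| < n}
  \mathrm{RERI}_{|S|}(S \mid \text{rest absent})$, which `decompose()`
  returns component by component.  A related recursion links orders:
  $\mathrm{RERI}_n = \mathrm{RERI}_{n-1}(\cdot \mid X_i{=}1)\, RR_{e_i}
  - \mathrm{RERI}_{n-1}(\cdot \mid X_i{=}0)$ for any pivot $i$.
* **Multiplicative index** — $I = RR_{\text{joint}} / \prod_i RR_{e_i}$,
  equal to 1 under exact multiplicativity.  Only $I_2$ is standard in the
  literature; the same ratio for $|S| > 2$ is implemented as the natural
  generalisation and documented as such.  When all single-factor RRs are
  at least 1, $I \ge 1$ implies $\mathrm{TotRERI} \ge 0$ (super-
  multiplicative effects are super-additive), which the test suite checks
  on random grids.

All measures are pure functions of a `rr_grid`, a validated map from all
$2^n$ patterns to positive RRs.  Patterns are enumerated by increasing
number of present factors, ties broken by the subset order of the factor
indices, so pattern order mirrors the canonical term order `A, B, C, A:B,
A:C, B:C, A:B:C` produced by an `A*B*C` formula.

## Why factors must be risk factors

A protective factor has $RR \in (0,1)$ while a risk factor has
$RR \in (1,\infty)$; additive contrasts across that asymmetry are
meaningless (two protective drugs with exactly additive effects would imply
a negative joint RR).  `check_risk_orientation()` flags any factor whose
single-factor RR is below 1, and the fitting pathway refuses to proceed
unless `reorient = TRUE`, which recodes flagged exposures to their
complement (`1 - x`, renamed `no_<factor>`) and refits.  At the grid level,
`reorient()` inverts the chosen bits and re-references every RR to the new
all-absent pattern; flipping twice restores the original grid exactly.  The
detection rule uses single-factor RRs at the reference of the other factors;
`strict = TRUE` additionally scans all strata and warns when a factor's
direction reverses across strata (qualitative interaction), in which case no
recoding can make it uniformly risk-conferring and the package defers to the
user rather than choosing a flip itself.

## Estimation pathways

**Saturated regression (`reri()`).**  The model must contain a term for
*every* non-empty subset of the exposures — main effects and all product
terms — plus any covariates.  Dropping a product term (for instance by
penalised selection) makes the pattern RRs, and hence every measure,
non-computable; the fitter therefore always saturates regardless of what the
formula contained.  Logistic regression yields odds ratios (a relative-risk
approximation for rare outcomes); Cox regression (Efron tie handling, the
standard default) yields hazard ratios.  Covariates enter the linear
predictor but stay out of the grid: the grid is covariate-conditional.
Every exposure pattern must be observed with at least one event, otherwise
the cell is unidentifiable and the fit aborts naming the offending pattern.

**Exported coefficients (`reri_from_coefs()`).**  A coefficient vector and
covariance matrix from a model fitted elsewhere give the same object.

**Contingency tables (`reri_from_counts()`).**  Per-pattern cases and
denominators give risks (or rates for person-time), RRs, and large-sample
log-RR variances ($1/a_p - 1/N_p + 1/a_0 - 1/N_0$ for subject counts,
$1/a_p + 1/a_0$ for person-time).  Cells are independent, but every log RR
shares the reference cell, so the covariance between two log RRs equals the
reference-cell variance component; the package includes this term, which
makes contingency standard errors agree asymptotically with the saturated
logistic model on the same data (the point estimates agree exactly, both
being saturated estimators of the same per-pattern risks).  A zero cell
makes the log-RR variance infinite and the RR zero, which no valid grid can
represent: the package warns, and the optional `+0.5` continuity correction
(off by default, always announced) is the way to proceed.  Odds-ratio mode
supports case-control-style input with a rare-disease warning.

## Delta-method inference

Every RERI-type measure is $N/D$ with $N = \sum_p c_p RR_p$ a signed sum of
pattern RRs and $D$ a re-referencing RR, and $RR_p = \exp(x_p'\beta)$ is
log-linear in the saturated coefficients.  The gradient is therefore
analytic: $\partial N/\partial \beta_T = \sum_p c_p RR_p x_p[T]$, with the
quotient rule for conditional measures.  `delta_ci()` propagates the
coefficient covariance through this gradient, $se = \sqrt{g'Vg}$.
Intervals are symmetric Wald on the RERI scale — the convention under which
published RERI intervals are symmetric around the estimate — while
single-pattern RRs/HRs and the multiplicative index, being log-linear, get
log-scale intervals that are exponentiated (hence asymmetric, e.g.
$e^{0.36 \pm 1.96 \cdot 0.09} = (1.20,\ 1.71)$).  The normal quantile is
computed exactly, not hard-coded at 1.96.  The same coefficient vector $c$
drives both the point estimate and the gradient, so the two cannot drift
apart; an independent finite-difference oracle in the test suite checks the
gradients to $10^{-6}$ relative tolerance, and delta standard errors are
checked against a 200-resample nonparametric bootstrap on an
$N = 20{,}000$ cohort (15% relative tolerance).

## The synthetic-cohort generator

`scenario_config()` defaults describe a cohort resembling the worked
example the package's defaults are calibrated to: three binary exposures
with prevalences 0.34 / 0.39 / 0.19, log-scale effects
$(0.36, 0.29, 0.41, -0.27, -0.23, -0.24, 0.92)$ for the seven saturated
terms, and a rare outcome with a marginal event fraction of 8%.  Survival
mode draws exponential event times with hazard
$\lambda_0 e^{\text{lp}}$ under administrative censoring at 15 years
(optional uniform drop-out); the baseline hazard is calibrated by exact
root-finding so the expected event fraction hits the 8% target.  Logistic
mode draws $y \sim \mathrm{Bernoulli}(\operatorname{expit}(\alpha +
\text{lp}))$ with $\alpha$ calibrated the same way; a log-binomial scheme
($P = \text{baseline} \cdot e^{\text{lp}}$) is available and errors, naming
the pattern, whenever a risk would exceed 1.  In each mode the generating
model matches the analysis model, so the analytic truth of every measure is
the grid of exponentiated generating coefficients — in logistic mode these
are odds ratios, and the simulation assesses the estimation machinery on
that scale rather than the rare-disease approximation.

Exposures are independent by default; an optional latent-Gaussian copula
(thresholded multivariate normal) induces dependence while preserving the
marginal prevalences.  Optional confounders mirror a typical adjustment
set: an age-like normal covariate (mean 53.4, sd 12.5, default log effect
0.07 per year, centred) and a four-level education-like category
(probabilities 0.26/0.41/0.18/0.15, default log effects 0, −0.1, −0.2,
−0.3).  These effect sizes are the package's own choice of plausible
confounder strengths; they matter only for robustness scenarios and are
fully configurable.

What the generator deliberately does **not** emulate: real cohorts have
non-exponential hazards, informative censoring, measurement error in the
exposures, and confounding structures richer than one continuous plus one
categorical covariate.  Passing simulations therefore demonstrate that the
estimators and intervals are correct *under the stated generating model*,
not that any particular real-data analysis is unbiased.

Randomness is counter-based: replicate $r$ under master seed $s$ uses the
derived seed $((s \bmod 46340) \cdot 46341 + r) \bmod (2^{31}-1)$, so
replicates are order-independent and a (seed, config) pair reproduces a
report exactly.

## The replication harness

`run_simulation_study()` generates, fits, and measures each replicate, then
aggregates per measure: bias against the analytic truth, the Monte-Carlo SE
of that bias, empirical vs mean model-based SE, and CI coverage with its
binomial MC-SE.  Replicates whose saturated model is unidentifiable (an
empty or event-free cell) are dropped and counted; more than 20% dropped
aborts the scenario as infeasible.  The shipped study sizes — 500
replicates of $N = 20{,}000$ in logistic mode for the calibrated scenario,
smaller cohorts for the null-effect checks — were chosen as the smallest
sizes at which coverage can be distinguished from nominal within binomial
Monte-Carlo error (at 500 replicates the MC-SE of a 95% coverage estimate
is about 1 percentage point).

## Numerical choices and edge cases

* Grid bound $n \le 16$: all $2^n$ enumeration is exact, no sparse
  approximation; epidemiological practice rarely exceeds 4–5 factors and
  exactness keeps the brute-force test oracles feasible.
* `classify()` defaults to tolerance 0 (classification by sign, the
  published convention); a tolerance parameter exists for numerical use.
* The decomposition identity is exact algebra; tests enforce it to
  $10^{-10}$ relative tolerance to leave room for floating-point
  accumulation on 64-pattern grids.
* Negative delta-method quadratic forms beyond $-10^{-10}$ raise an error;
  tiny negatives from rounding are clamped to zero.
* Reference RR must equal 1 exactly (within $10^{-12}$ on input); the
  constructor normalises it to exactly 1.
* Separation in the logistic fit (|coefficient| > 15 or non-convergence)
  is surfaced as a fit error rather than returned as a grid.

## Known limitations

* Binary exposures only: additive-interaction measures for ordinal or
  continuous exposures are a different, substantially harder problem and
  out of scope.
* Case-control designs are supported only through odds-ratio mode with the
  rare-disease caveat; no design-specific corrections are applied.
* Interaction estimation is power-hungry; with realistic cohort sizes the
  intervals on three-way measures are wide, and the package reports that
  honestly rather than shrinking them.
* No multiplicative analogue of the additive decomposition is implemented:
  only the multiplicative index itself is defined.
* Stratified (Mantel–Haenszel-style) pooling of tables is not provided;
  confounder adjustment belongs to the model pathway.

## A worked example

```{r example}
beta <- c(lowMD = 0.36, highBMI = 0.29, smoker = 0.41,
          "lowMD:highBMI" = -0.27, "lowMD:smoker" = -0.23,
          "highBMI:smoker" = -0.24, "lowMD:highBMI:smoker" = 0.92)
se <- c(0.09, 0.08, 0.18, 0.12, 0.30, 0.29, 0.45)
fit <- reri_from_coefs(coef_set(c("lowMD", "highBMI", "smoker"),
                                beta, diag(se^2)))
fit
summary(fit)
```

The total departure from additivity (TotRERI$_3 \approx 1.18$) is driven by
a strongly positive three-way interaction (RERI$_3 \approx 1.97$) partly
offset by negative two-way interactions in the strata where the third
factor is absent — exactly the pattern the decomposition makes visible.
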