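---
title: "Methods: estimating and triangulating genetically moderated treatment effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and triangulating genetically moderated treatment effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmte)
```

## The estimand

Pharmacogenetic analyses ask how much of a drug's benefit is forgone by
patients whose genotype blunts its effect. With a binary genotype `G`
(1 = treatment-enabling group, declared by the analyst — the package never
infers the coding), binary treatment `T`, outcome `Y`, measured covariates
`Z` and unmeasured confounders `U`, the working outcome model is linear with
a treatment-genotype interaction:

$$
E[Y \mid T, G, Z, U] = \gamma_{Y0} + \beta_1 TG + \beta_0 T(1-G)
 + \gamma_{YG} G + \gamma_{YZ} Z + \gamma_{YU} U .
$$

The estimand is the genetically moderated treatment effect
$\beta_{GMTE} = \beta_1 - \beta_0$: the average causal contrast between
receiving the full, genotype-enabled effect (`T* = TG = 1`) and the reduced
effect (`T* = 0`). Five assumptions index the estimators' validity:

* **PG1** — genotype independent of treatment given `U` ($\gamma_{TG} = 0$);
* **PG2** — genotype independent of confounders ($\gamma_{UG} = 0$);
* **PG3** — genotype independent of outcome given treatment and confounders
  ($\gamma_{YG} = 0$);
* **NUC** — no unmeasured confounder affects both treatment and outcome;
* **Hom** — no treatment effect in the reference genotype ($\beta_0 = 0$).

## The five estimators

Each estimator is a regression coefficient in an additive model that always
includes the covariates `Z`:

* `gmte1()` — coefficient of `T*` in `Y ~ T + T* + Z`: the genotype contrast
  among the treated. On a treated-only dataset this reduces to `Y ~ G + Z`.
* `gmte0()` — coefficient of `T*⁻ = (1-T)G` in `Y ~ T⁻ + T*⁻ + Z`: the same
  contrast among the untreated. Under PG1–PG3 it targets **zero**, so it is
  reported as a falsification estimate, never as a GMTE estimate.
* `rgmte()` — the robust estimate `gmte1 − gmte0`, either literally
  (`method = "difference"`, SEs added in quadrature because the two
  contrasts use disjoint outcome information) or as the coefficient of `T*`
  in the joint model `Y ~ T + T* + T̂* + Z` (`method = "regression"`, the
  default, where `T̂* = Ê[T*|G]`). Differencing removes bias channels that
  act equally in both treatment groups, so the estimate survives PG2/PG3
  violations whenever PG1 or NUC holds.
* `gmte_mr()` — the instrumental-variable (Mendelian randomization) route:
  coefficient of `T̂*` in `Y ~ T̂* + Z`, algebraically the Wald ratio of the
  genotype-outcome and genotype-moderator associations. Because `T* = TG`,
  the instrument denominator is exactly the treated fraction among carriers.
* `gmte_cat()` — the corrected as-treated estimate: coefficient of
  `T_cat = Ê[G|T=1]·T` in `Y ~ T_cat + Z`, i.e. the adjusted
  treated-vs-untreated difference rescaled by the carrier share among the
  treated. It inherits the full weight of the no-unmeasured-confounding
  assumption and is the canonical victim of confounding by indication.

On covariate-free data every estimator collapses to its closed-form
group-mean expression; the test suite checks this equivalence against
independent brute-force oracles.

### A note on the two robust-estimator routes

Without covariates the difference and regression routes agree to machine
precision (the joint design spans the saturated genotype-by-treatment
space). With covariates the joint model pools the `Z` slopes across
treatment groups while the difference route lets them differ, so the two
routes agree only up to an order-1/n discrepancy, a small fraction of the
standard error in practice. The regression route is the default because its
standard error comes from a single fitted model.

## Outcome scales and adapters

All estimates are reported on **collapsible** difference scales, so that
marginalising over independent covariates does not move the estimand and
uncorrelated estimates can be meaningfully pooled:

* continuous outcomes — mean differences from linear least squares;
* binary outcomes — risk differences, by default the average marginal
  effect (AME) from a logistic fit: for a binary regressor the average
  predicted-probability contrast, for a continuous one the average
  derivative, with delta-method standard errors propagated through the
  logistic information matrix. A linear probability model is available via
  `binary_method = "lpm"` and is the advised fallback when the logistic fit
  separates (a coded error is raised);
* time-to-event outcomes — additive hazard differences per year from a
  semiparametric additive hazards model with time-constant coefficients:
  the closed-form least-squares solution of the additive-hazards estimating
  equation, with a sandwich variance accumulated over event times. Risk
  sets are right-continuous (a subject is at risk at its own exit time) and
  tied times share one risk set. The constant-coefficient form — one hazard
  difference per regressor — is the collapsible analogue of a mean
  difference; time-varying coefficient curves are deliberately out of
  scope. Percent-per-year rendering (`as_percent()`) multiplies the
  estimate and SE by 100 and is a display transform only; percent and raw
  scales refuse to pool.

Left truncation and delayed entry are not modelled: time runs from each
subject's own origin. Cohort construction (prescription curation, ancestry
filtering, relatedness) is assumed done upstream.

## Combination and the heterogeneity gate

Estimates with disjoint assumption sets are only worth comparing if they are
statistically (nearly) uncorrelated. The robust and IV estimates are
asymptotically uncorrelated, and the corrected as-treated estimate is
uncorrelated with the treated-only and robust contrasts; both facts motivate
the five sanctioned combinations CAT/GMTE1, CAT/RGMTE, CAT/MR, RGMTE/MR and
CAT/RGMTE/MR. The treated-only contrast is never pooled with RGMTE or MR,
with which it shares most of its data. `ivw_combine()` pools $k \in \{2,3\}$
components by inverse-variance weighting and computes
$Q = \sum_i w_i(\beta_i - \bar\beta)^2 \sim \chi^2_{k-1}$ under homogeneity;
the gate passes when the Q p-value is at or above `alpha` (default 0.05,
configurable). Failing combinations are reported with their statistics and a
`no` flag rather than dropped, and the forest plot colours the two outcomes
differently, with the falsification estimate in its own colour.

Two approximations are accepted knowingly: the CAT-MR correlation is ignored
even though it is non-zero when the genotype predicts treatment (it is
practically negligible at realistic effect sizes, at the price of a modest
coverage dip for CAT/MR-type combinations when the genotype-treatment path
is strong), and combined-estimate confidence intervals ignore component
correlation throughout. When the genotype is independent of treatment and
the cohort is half treated, the pooled RGMTE/MR estimate converges to the
treated-only contrast per dataset; the test suite verifies the gap shrinks
with n.

## Confounder diagnostics

Each estimator has a matched falsification test: rerun its recipe with a
candidate confounder as the outcome (`confounder_test()`). Under the
estimator's assumptions the result targets zero, so a rejection flags a bias
channel that adjustment should close. The tested variable is always removed
from the adjustment set of its own test; for the corrected as-treated
estimator the genotype itself can be tested, probing carrier-share imbalance
between treatment groups. Binary candidates are tested on the
linear-probability scale. No multiplicity correction is applied by default
(`bonferroni = TRUE` tightens the verdict threshold only); the verdict warns
and never forces adjustment.

## The scenario simulator

`scenario_config()` parameterises the structural model

```
G ~ Bern(p_G);  Z ~ N(0,1);  U ~ N(0,1) + γ_UG·G
T ~ Bern(expit(γ_T0 + γ_TU·U + γ_TG·G + γ_TZ·Z + ε_T))
Y = γ_Y0 + β1·T·G + β0·T·(1−G) + γ_YG·G + γ_YZ·Z + γ_YU·U + ε_Y
```

and `run_mc()` reports, per estimator and per sanctioned combination, the
Monte-Carlo mean estimate, mean SE, empirical 95% CI coverage of the truth
(of zero for the falsification estimate) and heterogeneity-gate pass rates.
Runs are bit-reproducible from the seed; replicates in which an estimator
fails are excluded with a logged count, and more than 1% failures aborts the
run. The simulated unmeasured confounder is carried only as an `oracle`
attribute for recovery checks — estimators never see it.

### Default parameter choices

Defaults were fixed once, to represent a realistic pharmacoepidemiological
cohort, and the same values drive the acceptance checks:

* `n = 10000`, `reps = 500`, `p_G = 0.3`, true GMTE $\beta_1-\beta_0=-0.5$.
* `gamma_T0 = -2`: a baseline treatment rate near 12%. Most of a
  primary-care cohort is untreated; this is also the regime in which the
  treated-only and ratio-type estimators visibly diverge in precision,
  which a 50/50 split would mask.
* `gamma_TZ = gamma_YZ = 0.5`: moderate measured confounding.
* `gamma_YU = 0.5`: an outcome-only unmeasured variable, kept non-zero so
  that switching on `gamma_TU` creates genuine confounding.
* Violation magnitudes in the presets: `gamma_TG = 1` and `gamma_TU = 1`
  where active (strong enough that the biases they induce are first-order
  at 500 replicates), and `gamma_YG = -0.25` (a direct genotype effect
  half the size of the estimand, in the opposite direction to the
  treatment benefit, as a realistic pleiotropy magnitude).
* Scenario 5 routes the genotype-confounder leak through treatment
  (`gamma_UG = 1`, `gamma_TU = 1`, `gamma_YU = 0`): a leak into an
  outcome-affecting variable would be indistinguishable from a direct
  genotype-outcome path and would contaminate the within-treatment-group
  contrasts, which is scenario 1's job, not scenario 5's.
* Scenario 6 keeps the leak mild (`gamma_UG = 0.1`). The robust
  estimator's immunity under PG1 is an asymptotic property of the linear
  outcome model; a strong leak through the nonlinear (logistic) treatment
  model induces a second-order collider bias that would blur the
  scenario's purpose of isolating first-order violations.
* Homogeneity-violating scenarios (5, 6) use `beta0 = 0.25`,
  `beta1 = -0.25`, preserving the estimand.

### What the simulator does and does not emulate

It emulates genotype-driven effect heterogeneity, confounding by indication,
pleiotropy-like direct genotype effects, genotype-confounder leaks and
rare-variant precision loss (`maf_sweep()`), all with a continuous outcome.
It does not emulate binary or survival outcomes (the outcome adapters are
exercised by small purpose-built oracle fixtures in the tests instead),
covariate model misspecification, measurement error in `G` or `T`,
time-varying treatment, or selection/loss to follow-up. Passing simulation
tests therefore demonstrate the estimators' algebra and operating
characteristics under the structural model, not robustness to the many ways
real cohort data depart from it.

## Numerical and degeneracy policy

* Strata required by an estimator with fewer than two rows raise coded
  errors (`gmte_error_singular`) rather than propagating NaN.
* An instrument denominator below 1e-10 is a coded weak-instrument error;
  fewer than 10 treated carriers warns but never silently truncates.
* A constant outcome returns a zero estimate with a degenerate SE rather
  than failing.
* Model-based SEs are the default everywhere, matching the fitting recipes
  above; `robust = TRUE` switches the linear fits to HC3 sandwich SEs. The
  IV estimate's second-stage SE ignores first-stage uncertainty by
  construction and is anti-conservative in small samples.
* Avoided-event counts round half-away-from-zero, once, at the final
  integer step; intervals use the same rule, sign-preserving.
* Missing data policy is complete-case on mapped columns only, with the
  dropped-row count logged.

## Problem sizes used by the test suite

The acceptance-level simulation checks run all six presets at 500
replicates of n = 10,000 (the scale at which the documented
bias/coverage pattern is resolvable, including the deliberately small
scenario-4 robust-estimator bias); the carrier-frequency sweep uses 60
replicates per grid point, which is ample for standard-error orderings; and
the structural property checks use datasets of 80–8,000 rows. These sizes
are the package's own choices balancing resolution against run time.

## Known limitations

* The multi-level genotype case (allele dosage 0/1/2) is not implemented;
  analyses of several genotype groups proceed as repeated pairwise
  group-vs-reference runs on subset data.
* Pooling assumes exact zero correlation between components; a
  correlation-aware combination rule (e.g. Mahalanobis-type) is not
  provided.
* No sequential-testing or family-wise error control across the nine
  reported results.
* The additive-hazards fit assumes time-constant hazard differences and no
  delayed entry.
* Non-collapsible scales (odds ratios, hazard ratios) are deliberately
  unsupported.
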