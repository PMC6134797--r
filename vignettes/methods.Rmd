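---
title: "Prioritized block-wise Lasso: model, algorithm and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritized block-wise Lasso: model, algorithm and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorlasso)
```

## The model

`priorlasso` builds prediction models from covariates organised in $M$
blocks (clinical variables, mutation indicators, expression values, ...)
with a user-chosen priority permutation $\pi$. The premise is practical
rather than statistical: blocks differ in cost, availability and clinical
acceptance, and their predictive information overlaps. When information is
shared between blocks, the fitting procedure should credit it to the block
the user ranked higher.

The procedure is stepwise. Step 1 fits an L1-penalized model to block
$\pi_1$. Step $m$ fits block $\pi_m$ with the accumulated linear score of
steps $1..m{-}1$ entering the linear predictor as an *offset*, i.e. with
its coefficient fixed to 1 rather than re-estimated. Penalized estimation
then shrinks block $\pi_m$'s coefficients towards zero unless the block
explains outcome variability the earlier blocks could not. For the squared
error loss this is literally a Lasso on the running residuals; for
logistic and Cox losses the offset plays the same conditioning role on the
linear-predictor scale. The final model is the sum of all steps,
$\hat\eta_i = \sum_m \sum_j \hat\beta^{(\pi_m)}_j x^{(\pi_m)}_{ij}$
(plus the summed intercepts outside the Cox family), and decomposes
exactly into per-block contributions.

Assumptions worth stating: effects are linear on the link scale; censoring
is uninformative (survival family); covariates are complete — missing
values are rejected at load time, not imputed — and categorical variables
are pre-encoded as numeric indicators. A block fitted by the Lasso can
select at most $\min(n, p_m)$ variables, so the ceiling on model size
scales with the number of blocks.

## Over-optimistic offsets and their cross-validated repair

The in-sample score $\hat\eta_{m,i}$ is over-optimistic about what blocks
$\pi_1..\pi_m$ can explain for sample $i$, because $y_i$ helped estimate
it. Used as an offset, it therefore removes variability that later blocks
should have been allowed to claim, and the bias accumulates down the
hierarchy — lower-priority blocks can be squeezed out entirely. With
`cv_offsets = TRUE` the offset handed to step $m{+}1$ is instead computed
out-of-fold: the samples are split into `nfolds_offset` parts, the step is
refitted on each complement (re-running the full penalty selection inside
the fold, with its own nested lambda folds), and each sample is scored by
the fit that excluded its fold. Two consequences are deliberate design
choices:

* the *reported* coefficients of every step are always the full-data
  estimates — cross-validation only changes what downstream steps
  condition on, so the exported model is a single well-defined linear
  predictor;
* for the continuous and binary families the fold-specific intercepts are
  part of the cross-validated offsets (per-fold fits are centered on their
  own training part); the Cox family has no intercept and offsets are pure
  linear scores.

Whether the penalty should be re-estimated inside each offset fold or
frozen at its full-data value is a genuinely open design point; this
package re-estimates, on the argument that the offset should be the honest
out-of-fold prediction of the *procedure*, not of one fitted model. The
per-fold chosen penalties and coefficient vectors are kept in the returned
record, so the choice is fully auditable (and testable by explicit
fold-exclusion refits).

## Penalized core and numerical choices

Each step's path is solved by coordinate descent via `glmnet`: 100
penalties log-spaced from $\lambda_{\max}$ (the smallest value with an
all-zero penalized fit, offset included) down to $10^{-4}\lambda_{\max}$
($10^{-2}$ when $p_m > n$), convergence threshold $10^{-7}$, features
standardized to unit variance internally with coefficients reported on the
original scale. Exactly one fold partition is drawn per cross-validation
call and shared across the whole path. The CV loss is the family deviance:
squared error, binomial deviance, or the cross-validated Cox
partial-likelihood deviance.

Penalty selection is implemented independently of the solver's own
shortcuts so that its tie and cap behaviour is explicit: `"min"` takes the
penalty of minimal mean CV error, `"1se"` the largest penalty within one
standard error of that minimum, and ties are always broken towards the
larger (sparser) penalty. A per-block cap on non-zero coefficients
restricts the same selection to admissible path points; if none qualify
the block is left empty (largest penalty) — an empty step is legal and
simply passes its offset through.

Two conventions deserve a note:

* **Standardization.** Centering is intrinsic to the estimation;
  whether features should also be scaled to unit variance before fitting
  is study-dependent (cohorts are often standardized during
  harmonisation anyway). It is exposed as `standardize` in
  `fit_options()` (default `TRUE`) rather than fixed silently.
* **Seeds.** All randomness is fold assignment. Folds are drawn from the
  single `seed` in `fit_options()` with fixed per-step offsets
  (step $m$'s lambda folds from `seed + m`, its offset folds from
  `seed + 100m`, order-selection outer folds from `seed + 7777`), so any
  fit is reproducible from one integer. Survival folds are stratified on
  event status so every fold contains events.

`choose_order()` scores whole candidate priority orders by 5 outer folds
(default), refitting the complete pipeline per fold; inner lambda folds
are nested inside the outer training sets, so no held-out information
leaks into penalty selection. Survival loss uses the
Verweij–van Houwelingen construction (full-minus-training partial
likelihood), which is well defined for small held-out folds.

## Survival prediction and validation conventions

Absolute risks come from the Breslow cumulative baseline hazard
(increment = events / sum of $e^{\hat\eta}$ over the risk set, tied events
sharing the denominator) and
$S(t\mid x) = \exp(-H_0(t)e^{\hat\eta})$, evaluated as right-continuous
step functions. With all scores zero this reduces to the Nelson–Aalen
estimator, which the tests exploit as an oracle.

The validation suite follows the usual IPCW conventions, fixed here
explicitly because they matter at the third decimal:

* $\hat G$, the Kaplan–Meier estimate of the censoring distribution, is
  evaluated as a left limit $\hat G(t^-)$ wherever a subject's own event
  time enters a weight; ties between events and censorings are treated
  event-first.
* Uno's C truncates at a horizon $\tau$ (default: last observed event) and
  weights comparable pairs by $1/\hat G(T_i^-)^2$; score ties count 1/2.
* The Brier curve weights events by $1/\hat G(T_i^-)$ and survivors by
  $1/\hat G(t)$; the integrated Brier score is the trapezoidal time
  average over a grid of the event times, from 0 up to each of two
  horizons (the clinical horizon, default 2 time units, and the last
  validation event).
* Horizon TPR/TNR/AUC use the complete-case definition by default:
  cases are events by the horizon, controls are subjects observed beyond
  it, and subjects censored earlier are excluded; `ipcw = TRUE` switches
  to inverse-probability weights instead. The cutoff is the median score
  of the scored cohort.
* Risk groups come from an exhaustive search over ordered pairs of
  cutpoint candidates (midpoints between consecutive distinct training
  scores) maximising the three-group logrank $\chi^2$. Unconstrained, the
  maximum degenerates towards tiny extreme groups, so every group must
  hold at least 10% of the samples (`min_frac`). Statistic ties prefer the
  most balanced partition, then the smaller lower cutpoint. The partition
  is invariant under strictly monotone transforms of the score. Hazard
  ratios use the intermediate group as baseline with Wald intervals and a
  2-df likelihood-ratio test.
* The calibration slope is the Cox coefficient of the score as sole
  covariate (exactly 1 on training data for an unpenalized Cox score);
  "optimism" is the training-minus-validation slope difference.

## The synthetic generator

Because the package must be testable without any cohort download, the
generator is a first-class module with an explicit statistical contract:
latent standard-normal factors $Z$ ($n \times L$), features
$x_j = \lambda_j^\top Z + \varepsilon_j$ scaled to a configured marginal
variance, binary features by thresholding at a prevalence quantile, and
outcome generated from the true linear predictor
$\eta = \sum_m X^{(m)}\beta^{(m)}$ — Gaussian, logistic, or
Weibull/exponential survival times $h(t) = h_0 a t^{a-1} e^{\eta}$ with
uniform-window censoring whose upper bound is calibrated by bisection to
the target censoring fraction. Blocks loading on the same factors carry
redundant signal; that dial is what makes priority behaviour testable.
`aml_like_preset()` reproduces the shape of a multi-omics AML survival
study — blocks of 2 score indicators, 8 clinical, 40 binary mutation and
`round(15809 * scale)` expression features, ~50% censoring, redundancy
between score/clinical and mutation/expression pairs.

What the generator does *not* emulate: heavy-tailed expression marginals,
batch effects, block-wise missingness, informative censoring. Passing
tests therefore demonstrate algorithmic correctness and the claimed
qualitative behaviours (redundancy absorption, cv-offset contrast,
parameter recovery) under a clean generative model — not performance on
real cohorts.

## Problem sizes and limitations

The test suite exercises deliberately modest sizes chosen to make every
property cheap to verify many times over: oracle identities on 5–60
samples, simulation properties on $n = 100..600$ with tens of features,
and an end-to-end pipeline at $n = 447/250$ with a 79-feature expression
block (`scale = 0.005`) — the hierarchy's behaviour does not change with
the expression block's width, only its runtime.

Known limitations: blocks observed for only a subset of samples are not
handled (assign such data low priority and fit on the complete cases, or
impute upstream); no elastic-net mixing, adaptive weights or stability
selection; no post-selection inference — reported coefficients are
shrunken estimates without standard errors; competing risks and
time-varying covariates are out of scope.
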