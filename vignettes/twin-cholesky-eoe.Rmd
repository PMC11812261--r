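---
title: "Longitudinal twin ACE Cholesky models for emotional overeating"
author: "twinace authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal twin ACE Cholesky models for emotional overeating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific background

`twinace` implements the classical twin analysis of emotional overeating
(EOE) in children measured longitudinally — at 16 months with the 3-item
toddler adaptation of the Child Eating Behaviour Questionnaire (CEBQ-T)
and at 5 and 12 years with the 4-item CEBQ Emotional Overeating subscale,
each item a 1–5 Likert response and the subscale score the mean of
completed items (at least 2 of 3, respectively 2 of 4, must be
completed).

The twin design rests on the comparison of monozygotic (MZ) pairs, who
share all segregating genes, with dizygotic (DZ) pairs, who share on
average half. Under the equal-environments assumption — both kinds of
pairs share their trait-relevant rearing environment to the same extent —
a greater MZ than DZ resemblance implicates additive genetic variance
(A), equal MZ and DZ resemblance implicates the shared environment (C),
and whatever twin resemblance does not explain is nonshared environment
plus measurement error (E). Cross-twin *cross-time* correlations extend
the logic to stability: their MZ:DZ pattern attributes longitudinal
continuity in the phenotype to continuing A (2:1 pattern) or continuing
C (1:1 pattern).

## The model

Order the six observed scores of a pair as (twin 1 × waves, twin 2 ×
waves). With lower-triangular 3×3 path matrices $a, c, e$ and
$A = aa^\top$, $C = cc^\top$, $E = ee^\top$, the model-implied
covariance is

$$
\Sigma_r \;=\;
\begin{pmatrix}
A + C + E & rA + C\\
rA + C & A + C + E
\end{pmatrix},
\qquad r = \begin{cases}1 & \text{MZ}\\ 0.5 & \text{DZ,}\end{cases}
$$

with one phenotypic mean per wave, shared across twins and groups. The
Cholesky ("triangular decomposition") parameterization makes each wave
load on latent A/C/E factors originating at that wave and at all earlier
waves; diagonal paths are wave-unique effects, sub-diagonal paths are
carry-over effects, and $A, C, E$ are positive semi-definite by
construction, which removes all boundary handling from the optimizer.

**Likelihood.** Estimation is full-information maximum likelihood: each
pair contributes $-2\log$ of the multivariate-normal density of its
*observed* sub-vector under the zygosity-appropriate $\Sigma_r$ and mean
sub-vector. Internally, records are grouped by zygosity and missingness
pattern, and the likelihood is evaluated from per-pattern sufficient
statistics ($n_k$, mean, MLE covariance), which is algebraically
identical to per-row evaluation (the tests verify this against a direct
per-pair density oracle) and fast enough for numeric optimization at
cohort scale.

**Model ladder.** Before the ACE model, three baselines are fitted:
the fully saturated two-group model (per group 6 means + 21 covariance
elements; 54 parameters), sub-model 1a equating means and variances
across twin order within group (42), and sub-model 1b additionally
equating them across zygosity (36 under this implementation's constraint
set, which leaves all covariances free; see "Open decisions"). Nested
models are compared by $\Delta\chi^2 = \Delta(-2LL)$ on
$\Delta\mathrm{ep}$ degrees of freedom and by AIC
$= -2LL + 2\,\mathrm{ep}$. Degrees of freedom for a fit are the number of
non-missing observations minus ep.

**Standardization.** At wave $w$ the share of variance contributed by
the factor originating at wave $k \le w$ through matrix
$m \in \{a, c, e\}$ is $m_{wk}^2 / V_w$ with
$V_w = \sum_m \sum_{k\le w} m_{wk}^2$; the nine shares per wave sum to
one. [standardize()] reports both these per-origin shares (the numbers
shown on longitudinal path diagrams) and per-component totals (the usual
standardized A/C/E). Falconer's algebraic estimates
$A = 2(r_{MZ} - r_{DZ})$, $C = r_{MZ} - A$, $E = 1 - r_{MZ}$ are
provided as a cross-check.

## Data preparation choices

EOE scores are regressed per wave on sex (binary indicator) and age at
that wave, pooling both twins of each pair, and the residuals are used
for modelling. Age is perfectly shared within pairs and sex is shared by
all same-sex pairs, so leaving these covariates in would inflate C. The
regression is fitted separately per wave (ages are recorded in different
units per wave — months at 16 months, years later — and never mix), by
ordinary least squares without a clustering correction: only point
residuals enter the models, so the OLS point fit suffices. Twin order
within a pair is taken as given by the input file; all cross-twin
statistics are made order-invariant by double entry.

Twin correlations (intraclass, cross-twin cross-time, within-twin
cross-time) are double-entry Pearson correlations on pairwise-complete
data per cell — mirroring FIML's use of partial records — with Fisher
$z$ intervals, $\tanh(\operatorname{atanh} r \pm z_{\alpha}/\sqrt{n-3})$,
using the number of contributing pairs (doubled entries counted once) as
effective $n$. Within-twin cross-time correlations are reported per
zygosity and pooled, since published tables sometimes print pooled
values in both blocks.

## Numerical choices

* Optimizer: BFGS with finite-difference gradients (step $10^{-6}$),
  relative tolerance $10^{-10}$, restarted once from its own optimum;
  the ACE model uses 5 starts by default (a moment/Falconer-based start
  plus seeded random perturbations, s.d. 0.15).
* Non-positive-definite proposals (possible for the saturated baselines,
  whose covariances are free, and for observed sub-matrices) return a
  graded penalty $10^{10}(1 + |\lambda_{\min}|)$ rather than an error;
  non-finite proposals return $10^{12}$. A fit is flagged converged only
  if the optimizer reports success and the optimum is below the penalty
  range. Log-variance parameters are capped at $e^{30}$ to guard
  finite-difference excursions.
* Starting covariances are built from pairwise-complete pooled moments,
  eigenvalue-floored and shrunk 10% toward the identity so starts are
  always positive definite (pairwise-complete moment matrices need not
  be).
* Sign convention: the likelihood is invariant to flipping any Cholesky
  column, so columns are reported with non-negative diagonals.
* Model comparison treats $\Delta\chi^2 < -10^{-6}$ as an optimizer
  failure (error), and clamps smaller negative rounding noise to zero.
* Confidence intervals: profile likelihood by default — bounds where the
  profiled $-2LL$ rises by $\chi^2_1(0.95) = 3.841$ — profiled by
  coordinate-fixing for parameter targets and by a quadratic-penalty
  ramp for function targets (e.g. standardized shares, whose intervals
  are clipped to $[0,1]$). A percentile bootstrap over pairs, resampled
  within zygosity, is the documented fallback when profiling fails.

## Refitting from published summary statistics

When raw pair data are unavailable, published per-zygosity 6×6
correlation matrices are, under completeness, the sufficient statistics
of the Gaussian likelihood up to scale. `fit_published_ace()` treats the
published Gemini EOE correlation matrices as complete-data sample
covariances with unit variances, weights the groups by the published
baseline pair counts (749 MZ, 1616 DZ), and fits the ACE Cholesky by
two-group maximum likelihood. This reproduces the published early-life
decomposition closely: additive-genetic share ≈ 10% and
shared-environment share ≈ 87% at 16 months, wave-unique C ≈ 79% at
5 years, and a 16 months → 5 years shared-environment carry-over share
of ≈ 9%.

Two caveats, decided here and worth stating plainly:

* **Wave-unique vs total shares.** Published per-wave percentages for
  this design sum to ~100% only when the per-wave A and C figures are
  read as *wave-unique* squared paths ($a_{ww}^2/V_w$, $c_{ww}^2/V_w$)
  alongside the separately printed carry-over shares. The package
  therefore reports both readings, and the summary-statistics
  reproduction targets the wave-unique one. At the first wave the two
  readings coincide.
* **The 12-year genetic share is not recoverable from printed pairwise
  correlations.** The printed 12-year intraclass correlations (MZ 0.95,
  DZ 0.73) force a total additive-genetic share near
  $2(0.95-0.73) = 0.44$ in *any* fit that respects them — the
  maximum-likelihood solution here gives 0.44 total (0.40 wave-unique)
  — whereas the published model estimate from raw data is 34%. Raw-data
  FIML uses all partially observed pairs, so its model-implied 12-year
  correlations need not match pairwise-complete double-entry estimates;
  with only ~20% of pairs observed at 12 years the two can differ
  materially, and no reweighting of the printed matrices (an
  attrition-pattern FIML variant was tried during development) moves
  the fit toward 34%. The package reports the honest value from the
  printed statistics rather than tuning toward the raw-data figure.

## The synthetic cohort generator

`simulate_cohort()` draws latent trivariate pair vectors from
$\Sigma_r$, adds centred sex and age effects, optionally discretizes to
Likert items, and applies pair-level wave retention. Design choices:

* **Missingness** is wave-level and pair-level (both twins missing
  together, as with questionnaire non-return), independent across waves
  and pairs, and independent of the phenotype (MCAR). Nothing about
  informative dropout is emulated.
* **Likert discretization**: each wave has 3 or 4 items; an item's
  response is 1 + the number of its four equally spaced cutpoints lying
  below the latent value, and items are staggered by small offsets so
  the item mean forms a fine monotone staircase. Thresholds are
  calibrated so wave score means land near the published 1.64 / 1.57 /
  1.75. With means that low, roughly half the mass sits at the floor of
  the 1–5 scale, which attenuates Pearson correlations of the
  discretized scores by up to ~0.03 relative to the latent scale.
* **Calibration** (`data-raw/calibrate_gemini.R`): because the published
  twin correlations are properties of *observed* scores, the default
  generating paths of `gemini_like_config()` are calibrated by a
  fixed-point iteration — fit paths to latent targets, simulate, measure
  observed double-entry correlations, shift the latent targets by the
  residual against the published matrices — run once and frozen. After
  calibration the simulated cohort's correlation matrices match the
  published ones to within ~0.01 at large n (the latent paths, e.g. a
  smaller latent E, differ from the observed-scale decomposition
  precisely by the attenuation this compensates). A consequence of the
  floor is a ceiling on attainable observed correlations: an observed
  intraclass of 0.98 (the published 5-year MZ value) sits at that
  ceiling, and the simulated value can fall short of it by up to ~0.02.
* **Study conditions**: 749 MZ + 1653 DZ pairs (2402 pairs, 31.2% MZ),
  retention 3784/4804, 2064/4804 and 964/4804 reproducing the published
  per-wave individual counts in expectation; ages ~N(15.8, 0.1) months,
  N(5.15, 0.13) and N(12.69, 0.43) years; small centred covariate
  effects (sex 0.05, age 0.10/0.10/0.05 per unit) standing in for the
  sex and age associations the residualization step exists to remove —
  values chosen once as plausibly small for this phenotype, since the
  cohort publications do not report them.
* **Not emulated**: item-level response distributions (unpublished; only
  subscale means/SDs are targeted — the simulated score SDs run ~0.1
  above the published ones because matching them exactly would deepen
  the discretization attenuation), rater effects, zygosity
  misclassification, MNAR dropout, sibling or parental phenotypes.
  Passing tests therefore show estimator correctness under the stated
  generative model, not robustness to those real-data features.

## Problem sizes used by the test suite

Module tests use cohorts of 40–12,000 pairs; estimator-recovery checks
use 2,000 MZ + 2,000 DZ pairs with the cohort-like retention schedule
(1, 0.7, 0.4) across 20 seeds; correlation-pattern checks use 20,000
pairs per group; generator-calibration checks use 16,000 + 34,000 pairs.
These sizes were chosen so that Monte-Carlo error is small relative to
the tolerances being asserted while the whole suite stays comfortably
runnable on a laptop.

One statistical limit is documented rather than hidden: with 60%
attrition at the third wave, the ML estimator's sampling standard
deviation for the wave-3 standardized A and C shares at these group
sizes is ~0.03 (measured across seeds; bias < 0.01). A per-seed
recovery bound of ±0.05 over 20 seeds is therefore not attainable by an
unbiased estimator — about one seed set in ten would satisfy it — and
the corresponding worst-case assertion in the acceptance tests is
expected to fail while the aggregate (mean-over-seeds) recovery passes
comfortably.

## Open decisions

* Whether the sex/age regression should be per wave or joint is not
  dictated by the design; per-wave is used (units differ per wave).
* Sub-model 1b's constraint set ("equal means and variances across
  order and zygosity") leaves covariances free, giving 36 parameters;
  published tables for this design sometimes print a smaller count that
  is not arithmetically recoverable from the stated constraints, so
  `count_free_parameters()` reports the implemented count.
* Twin order is treated as given by the data file; double entry makes
  every reported statistic invariant to it.

## Known limitations

Ordinal-threshold (liability) likelihoods on the raw Likert items are
out of scope — scores are treated as continuous after residualization,
as is standard for CEBQ subscale means. ADE, sex-limitation and
gene–environment-interaction models, definition variables, and simplex
or common-pathway alternatives to the Cholesky are not implemented. The
equal-environments assumption is taken, not tested.
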