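---
title: "Environmental favourability modelling and transferability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environmental favourability modelling and transferability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(favourability)
```

## The model and its assumptions

The package models per-cell presence/absence of a species on a regular
grid (nominally 8-km cells, matching the resolution of downscaled
meteorological products) with a logistic GLM: outcomes are independent
Bernoulli draws given the cell's covariates, and the logit of the
presence probability is linear in the covariates,

$$ y = \beta_0 + \sum_i \beta_i x_i, \qquad P = \frac{1}{1 + e^{-y}}. $$

`P` is not directly comparable between datasets: a model trained where
the species was recorded in 70% of surveyed cells and one trained at 10%
prevalence put the same environment on different probability scales. The
**favourability function** removes that dependence by expressing the
odds of presence relative to the odds at the training prevalence
$n_1/n_0$ (presences over absences among surveyed cells):

$$ F = \frac{P/(1-P)}{n_1/n_0 + P/(1-P)} = \frac{e^{y}}{n_1/n_0 + e^{y}}. $$

Three consequences drive the package design, and are enforced as tested
invariants:

- $F = 0.5$ exactly where $P$ equals the training prevalence, so the
  conventional classification threshold $F \ge 0.5$ means "more
  favourable than the average surveyed condition";
- $F$ is strictly increasing in $P$, so any rank-based evaluation (AUC)
  is identical on the $P$, $y$ and $F$ scales;
- with $n_1 = n_0$ the transform is the identity.

Because the anchor $n_1/n_0$ is part of the model's meaning, it travels
with the coefficients (`coefficient_set` stores `n1`, `n0`), and
transferring a model to a new region keeps the training anchor by
default. Published coefficient tables usually omit $n_1, n_0$; such
models can only be projected after the user supplies an explicit
prevalence (`prevalence_source = c(n1, n0)`), and the pipeline re-anchors
on the target data's own prevalence when nothing else is available,
logging that it did so.

## Fitting, standardization and stepwise selection

`fit_logistic()` delegates the maximum-likelihood fit to a binomial GLM
with IRLS (relative deviance tolerance `1e-8`, at most 100 iterations).
Covariates enter the optimizer standardized — raw environmental units
(mm of annual precipitation against fractions of a degree of latitude)
can differ by five orders of magnitude and produce badly conditioned
information matrices — and both coefficients and their covariance are
mapped back to raw units afterwards, so reported coefficients are on the
natural scales of the variables. Standard errors on the raw scale
(`$std_errors`) come from propagating the covariance through the same
linear map.

Degenerate inputs fail loudly: a covariate constant over the usable
cells, or an aliased pair, is an error naming the variable; quasi-complete
separation (standardized coefficients diverging beyond ±15, i.e. odds
ratios beyond e^15 per SD) raises a classed warning
(`fav_separation`) rather than silently returning huge coefficients.

`forward_stepwise()` starts from the intercept-only model and repeatedly
admits the candidate with the smallest likelihood-ratio p-value (1-df
chi-square on the deviance drop) while that p-value is below
`entry_alpha` (default 0.05). Published favourability models report the
*order of inclusion* of each variable, so the selector records the
iteration at which each variable entered. The entry criterion itself is
not prescribed by the models this package packages as fixtures; the
likelihood-ratio rule is the simplest one consistent with ranked forward
inclusion, and an AIC mode is offered for users who prefer
information-criterion selection. Backward elimination and bidirectional
search are deliberately out of scope.

## Evaluation suite

Discrimination (not calibration) is the design focus. At a threshold
(default $F \ge 0.5$; ties classify as present, a deterministic and
documented choice) the confusion matrix yields sensitivity, specificity,
PCC/overall accuracy, PPP, NPP, TSS $=$ sensitivity $+$ specificity
$- 1$, and Cohen's Kappa. Any index whose denominator is zero is
reported as `NA`, never as 0 — a degenerate all-absent prediction must
not score a fake perfect PPP. Threshold policies: a fixed value,
the observed prevalence, or the TSS-maximizing observed score.

AUC is computed from the rank-sum statistic with midranks, which equals
exhaustive presence-absence pair counting with half-credit ties; the test
suite asserts that equality to 1e-12 against a brute-force oracle on
hundreds of tied instances.

TSS and AUC are carried because they are largely insensitive to
prevalence, unlike Kappa and PCC. This is itself a tested property:
randomly discarding half the absences (which shifts prevalence) moves
TSS by sampling noise only, while Kappa shifts systematically — the
suite asserts the mean absolute TSS change stays below Kappa's.

Whether indices are computed on training data (resubstitution) or on
held-out data is the caller's choice; `evaluate_model()` scores whatever
grid and observations it is given. Resubstitution is the default
reading in the model-comparison helpers, matching how transferred and
locally refitted models are usually contrasted in the favourability
literature.

## Synthetic landscapes

No field dataset ships with the package (the survey data behind the
packaged coefficient tables is unpublished), so all empirical claims are
exercised on synthetic landscapes the package can regenerate from a seed:

- **Covariates** are Gaussian white noise smoothed with a separable
  Gaussian kernel (sd = `autocorrelation_range` in cells, truncated at
  3 sd, renormalized at the borders), then rescaled linearly so the
  field's min and max equal the declared range exactly. This is the
  simplest mechanism that yields controllable spatial autocorrelation —
  verified by lag-1 Moran's I against white noise — without adding a
  geostatistics dependency. It does not emulate anisotropy, elevation
  gradients, or the spatial covariance structure of real climate fields.
- **Latitude** is generated as the cell-centre y-coordinate, not a random
  field: it is a spatial coordinate.
- **Outcomes** are independent Bernoulli draws from a known logit-linear
  truth, optionally with clamped (saturating) responses. One cell is one
  trial; the aggregation of sub-cell survey stretches into cells is an
  assumption, not something the simulator models. There is no
  nondetection error and no spatial dependence in the outcomes beyond
  what the covariates induce — so passing tests demonstrate correctness
  of the machinery under the stated model, not robustness to detection
  failure or residual autocorrelation in real surveys.

### The edge-of-range scenario

`edge_scenario_config()` encodes the package's standing benchmark for
transfer failure, emulating a rainy northern slope versus a drier
southern slope of the same mountain range: two 50×50-cell regions share
the truth

$$ y = -11.5 + 0.01 \cdot \min(\mathrm{Prec}, 1000) + 0.03 \cdot \mathrm{DPre} $$

with training precipitation spanning 500–1000 mm and target
precipitation 1500–2500 mm (disjoint; rain days `DPre` span 80–180 in
both). The numbers were chosen once to make a realistic mid-prevalence
training region (the intercept centres the training logit near zero, so
training prevalence varies around one half from seed to seed) in which
precipitation is the dominant, genuinely linear predictor — while in the
target region the clamp binds everywhere, precipitation carries no
signal, and a transferred linear precipitation term contributes about
±5 logits of pure extrapolation noise that swamps the transferable
rain-day signal. Altitude, radiation and latitude ride along as inactive
candidates for the selection machinery.

Under this design the transferred model's AUC on the target region drops
to near 0.5 while a locally refitted model keeps the rain-day signal
(AUC around 0.63) — the desk-scale restatement of transfer failure under
shifted covariate ranges. The published headline AUCs of the real
models (0.534 transferred versus 0.754/0.887 refitted) require the
unpublished survey data and are therefore not asserted anywhere; the
package reproduces the *phenomenon*, not those numbers.

Two design details matter for fairness of that comparison:

- both the transferred and the locally fitted model are scored on an
  **independent realization** of the target region. Scoring the local
  model on its own training cells gives it a small resubstitution
  optimism that is invisible at a glance but systematic; with held-out
  scoring, exchangeable regions give an expected AUC difference of
  exactly zero by symmetry, which the control experiment verifies.
- extrapolation diagnostics (`coverage_diagnostics`: per variable, the
  fraction of target cells outside the training range) are computed on
  every transfer, operationalizing *why* a transfer failed rather than
  only that it failed.

## Numerical choices

- `P` is clamped to `[1e-12, 1 - 1e-12]` before forming odds, so extreme
  logits give favourability 0 or 1 instead of `NaN`; the identity
  `favourability(P, n, n) = P` then holds to 1e-12 at the boundary and to
  machine precision inside it.
- Classification ties at the threshold go to "present"; AUC ties get
  half credit via midranks.
- All generators are pure functions of (configuration, seed); the
  pipeline derives per-stage seeds from one master seed and writes an
  md5 manifest, so a full run is reproducible checksum-for-checksum.

## Packaged published models

`desman_models()` returns the three published Pyrenean Desman
favourability models as fixtures, stored exactly as printed: the
transferred Spanish model (8 variables, constant −44.63) and the two
French refits (6 variables; 5 variables including latitude). Printing
quirks are preserved, not repaired: the French constants were printed
parenthesized (481, 496.9) with ambiguous sign convention, the
with-latitude model lists rank 3 twice and no rank 4
(`rank_consistent = FALSE` flags this), and the altitude code `Alti250`
is kept verbatim. No training prevalence was published, so these
fixtures cannot be projected to favourability without a user-supplied
anchor. Their coefficient scales differ wildly between models (e.g.
solar radiation −153.6 versus 0.013); units were not restated in the
source and the fixtures do not rescale anything.

## Problem sizes

The test and acceptance runs use grids of 2 000–10 000 cells, 20–50
replicates per stochastic property, and 100 randomized instances for the
AUC oracle equivalence — sizes at which every Monte-Carlo bound in the
suite has comfortable margin while a full run completes in seconds.

## Known limitations

- No spatial autocovariate or autologistic term: residual spatial
  dependence in real survey data will make the Bernoulli likelihood
  overconfident.
- No detection model: nondetection is absorbed into the response.
- No calibration/reliability assessment, no regularized fits, no
  maximum-entropy comparison, and no temporal (climate-scenario)
  projection — though swapping covariate grids in `transfer_model()`
  gives the mechanics for the latter.
- Raster I/O is plain ESRI ASCII grid, one layer per file.
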