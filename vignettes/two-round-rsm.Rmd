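---
title: "Two-round response-surface regression of microalgal bioenergetics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-round response-surface regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

*Chlamydomonas reinhardtii* adjusts its photosynthetic and respiratory
machinery to the environment it grows in. Quantifying that plasticity means
asking which of several culture factors — light intensity, acetate (the
organic carbon source of mixotrophic growth), CO2 regime, nitrate and
ammonium — actually drive six bioenergetic responses: dark respiration (CR),
the maximal activities of the cytochromial and alternative mitochondrial
pathways (MA_CYT, MA_ALT), the PSII quantum yield and non-photochemical
quenching under high light (PHIPSII800, NPQ800), and gross photosynthesis
(P800). Testing factors one at a time cannot see interactions and wastes
runs, so the screening is organized as a design of experiments (DOE)
followed by response-surface multiple regression.

`chlamyRSM` implements that workflow end to end: design construction,
effect encoding, least-squares fitting with the full ANOVA diagnostic set,
a two-round model selection, simulation of factor profiles and their
optima, and validation by cross-validation and against newly measured
factor combinations. A synthetic-data generator stands in for the raw
measurements so that every stage is testable.

## The model

Each response is modeled as a second-order polynomial in the factors
(Taylor screening model):

$$\hat y = b_0 + \sum_i b_i x_i + \sum_{i<j} b_{ij} x_i x_j +
  \sum_i b_{ii} x_i^2$$

with three term forms per factor pair: linear, quadratic (continuous
factors only) and pairwise interaction. For the five study factors this
gives 5 + 4 + 10 = 19 candidate effects.

Encoding conventions (`build_model_matrix()`):

* linear continuous terms enter **uncentered**, so coefficients print in
  the units of the published equations;
* quadratic and interaction terms are centered at the arithmetic mean of
  the factor **over the rows actually fitted** — a response with missing
  runs therefore carries slightly different centering constants than a
  complete one, which is visible in the published equations themselves
  (the dark-respiration model, fitted on 40 of 42 runs, centers acetate at
  0.463 g/L where the complete-data models use 0.488 g/L);
* the two-level ordinal CO2 factor enters as an indicator of its high
  level (1.5%), and its interactions as indicator × centered partner. A
  consequence worth knowing: the indicator interaction of a factor with a
  balanced two-level ordinal correlates about $1/\sqrt{2} \approx 0.71$
  with the factor itself. This is an artifact of the encoding, not a
  deficient design, and `effect_correlations()` reports it as such.

## Design construction

`build_design()` assembles a 42-run design in three layers:

1. a regular two-level fractional-factorial backbone (a resolution-V half
   fraction for five factors) on the factor extremes;
2. seven replicated center points — continuous factors at their range
   midpoints. CO2 has no midpoint; the center replicates alternate between
   its two levels (4 low / 3 high), which is the least-assuming reading of
   the original design and still supplies pure-error degrees of freedom at
   both regimes;
3. the remaining runs as *extra points* drawn from a pool of factorial
   corners, axial points (one factor at an extreme, the rest centered) and
   Box-Behnken-style edge points (two factors at extremes).

The extra points are placed greedily, then refined by exchange passes, to
maximize the log-determinant of the cross-product of the full 19-effect
model matrix on range-scaled factors. This information criterion is what a
computer-generated optimal screening design targets; we adopted it after
finding that selecting extras purely by minimizing pairwise effect-column
correlations produced designs that were *too interior*: their prediction
variance was so low that realistic noise swamped the weaker true effects,
which no correlation diagnostic reveals. The D-information score keeps the
main effects near-orthogonal anyway (maximum pairwise |r| ≈ 0.05 on the
default design, threshold 0.10 in the tests) while placing enough mass at
the extremes to give each response the signal-to-noise the original study
reports. All randomness is confined to a seeded scan order used for
tie-breaking, so a seed fully reproduces the table.

## Fitting and diagnostics

`fit_ols()` is QR least squares plus the complete diagnostic battery, each
piece defined exactly as used downstream:

* **SS decomposition** — total = model + error; with replicated factor
  combinations, error further splits into pure error (within-replicate
  deviations from group means, i.e. the error SS of a saturated model) and
  lack of fit. Identities are asserted on every fit at relative tolerance
  1e-8.
* **R², adjusted R²** — adjusted R² is computed as 1 − error MS / total MS.
* **RMSE_F, MAE_F** — RMSE_F is the square root of the error mean square;
  both are also expressed as a percentage of the *average scale*, the mean
  minus the minimum of the response values (rounded to whole percent for
  display).
* **AICc** — Gaussian likelihood with ML variance,
  $n\log(2\pi\,\mathrm{SSE}/n) + n + 2p + 2p(p+1)/(n-p-1)$ with
  $p = k + 2$ (intercept and variance count as parameters), matching the
  convention of mainstream DOE software so that within-response
  comparisons behave familiarly. A non-positive penalty denominator
  returns +Inf with a warning.
* **β-weights** — coefficients refitted after standardizing every effect
  column and the response to unit sample variance (n−1 denominator).
  Constructed second-order columns are standardized *as columns*, not
  rebuilt from standardized factors.
* **per-effect ANOVA** — effect SS by deprivation: the increase in error
  SS when the model is refitted without the effect's column (columns
  fixed, centering not redone), on 1 DF against the full model's error
  MS. The full-model denominator is a documented choice; the original
  description defines the SS but not the denominator.
* **whole-model ANOVA** — model MS over error MS on (k, n−k−1) DF.

The significance cutoff is 0.05 throughout, with no multiple-testing
correction — deliberately mirroring the original analysis, whose purpose
is screening rather than confirmation.

## Two-round selection

**Round 1** (`stepwise_forward()`): greedy forward selection over the 19
candidates by minimum AICc, with the "combine" heredity rule — adding a
second-order effect implicitly adds any absent parent linear terms, and it
is the AICc of the combined addition that competes. Ties prefer the
lower-order term, then enumeration order. Selection stops when no addition
lowers AICc.

**Round 2** (`backward_prune()`): the round-1 model is pruned by repeatedly
removing the term with the highest per-effect p-value (recomputed each
step; ties remove the higher-order term first). A tentative removal is
rejected — and pruning stops — if the reduced fit shows a significant
lack-of-fit test (p ≤ 0.05) or an R² below the floor. The floor is 0.60
when the round-1 model reaches it; otherwise it is the round-1 R² minus a
slack of 0.05, so a response that never fits well (NPQ is the study's
example) is pruned against its own attainable R² rather than an impossible
one. The slack value is a documented guess: the original account describes
the relaxed floor only parenthetically. After pruning, linear parents of
any retained second-order term are restored, so final models respect
heredity.

### What the stopping rule can and cannot do

A property of this rule worth stating openly, because the package's own
simulations expose it: when a response fits well (true R² ≈ 0.8, as for
CR), the R²-floor criterion tolerates the removal of *genuinely active*
effects — R² can fall from 0.8 a long way before hitting 0.60. Retention of
the weaker true effects then hinges entirely on the lack-of-fit test
firing at the right step, and with the pure-error degrees of freedom a
42-run design can carry (5–14), that test has only moderate power. Across
noise realizations at the study's error scales, the weakest true CR effect
(light) survives round 2 in roughly half to two thirds of runs, not
always; the original single-realization analysis retained it because its
lack-of-fit p-value happened to cross 0.05 at that step. This is a
statistical property of the published procedure at these noise levels, not
an implementation artifact; the test suite measures it rather than hiding
it.

## Synthetic data

`generate_responses()` emulates the study's measurement table: predictions
from the six published response models plus independent homoscedastic
Gaussian noise, with per-response SDs defaulting to the published fitted
RMSE_F values (CR 2.9, MA_CYT 3.5, MA_ALT 3.0, PHIPSII800 0.068, NPQ800
0.084, P800 19.6 — a single error scale per response is all the source
reports, so a homoscedastic model is the simplest consistent choice). The
default missing pattern reproduces the study's: CR unmeasurable on runs 14
and 28, MA_CYT on run 26. The two fluorescence indices are truncated at
zero — a physical constraint the source never needed to address — and the
number of truncated values is flagged. `generate_validation_set()` draws
new combinations uniformly (CO2 fixed at 1.5%, as in the study's
validation cultures) with replicate noise proportional to the prediction
(19.7% relative SD for NPQ800, 9% otherwise, the study's replicate
spreads).

What the generator does *not* emulate: possibly proportional measurement
error in the DOE runs themselves (the printed replicate RSDs hint at it,
but no per-run replicates exist to decide), run-order or batch effects,
and any model inadequacy — the generative truth *is* the published model.
Passing recovery tests therefore demonstrate that the pipeline finds
structure of the published kind at the published noise; they do not
certify behavior under misspecification.

## Profiles, optima, validation

`profile_curve()` evaluates a model along one factor with the others fixed
(by default at the model's fit-sample means, the convention of the
original simulations). For a quadratic profile the optimum is closed-form:
$x^\* = c - b_{\mathrm{eff}}/(2a)$, where $a$ is the quadratic
coefficient, $c$ its center, and $b_{\mathrm{eff}}$ the effective linear
coefficient after substituting the fixed values into interactions. The
tests cross-check every vertex against a 100,001-point grid search.
Confidence bands are omitted for the packaged published models: they would
require the original data's covariance, which printed coefficients do not
carry; refitting on a supplied design + response table recovers them in
principle.

`kfold_cv()` refits on each training complement — recomputing centering
constants on the training rows, so no information leaks from held-out
runs — and reports both fold-averaged and pooled MAE/RMSE (the study
reports fold averages; the two coincide for equal folds). Fold assignment
is a seeded random near-equal partition, or an explicit vector when one
wants the study's own subsets. `experimental_validation()` scores a model
against measured combinations (packaged: the study's 8 validation points;
the respiratory responses were measured on the first 6 only, and points
without a measurement are skipped with a warning).

## Numerical choices and degenerate inputs

* Singular systems are an error naming the aliased columns — never a
  silent pseudo-inverse.
* Constant effect columns on the fit rows are an error at encoding time;
  constant columns in correlation diagnostics are reported as undefined
  pairs rather than propagating NaN.
* Lack of fit is reported "unavailable" (not an error) without replicates
  or with non-positive lack-of-fit DF.
* A constant response yields an empty model, flagged; a response with
  fewer than 10 measured rows is skipped with a warning.
* Parameterization invariance: re-centering second-order columns changes
  coefficients but not fitted values or the SS decomposition (asserted at
  1e-8).

## Problem sizes used by the test suite

Stochastic properties are checked at fixed seeds with: 500 null-response
stepwise runs (median selected size ≤ 2), 200-seed recovery and pruning
simulations, 1000-simulation calibration of the lack-of-fit rejection rate
and of the whole-model p-value null distribution, 100-seed cross-validation
error tracking, and 10,000-row Monte-Carlo checks of the noise generator.
These sizes give the assertions comfortable margins while keeping a full
run of the suite around two minutes.

## Known limitations

* The design generator emulates the *structure* of the original 42-run
  design, not its exact coordinates (which live in a supplementary
  spreadsheet); analyses that depend on the exact original design accept a
  user-supplied design CSV instead.
* AICc values are comparable within a response only; the packaged
  registry stores printed coefficients at printed precision, so
  round-trip refits are exact to ~1e-6, not machine precision.
* The two-round procedure is greedy and does not backtrack, by design —
  it formalizes a sequential trial-and-error protocol, and its retention
  behavior at high R² is as discussed above.
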