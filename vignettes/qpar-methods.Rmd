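---
title: "Pattern-activity modelling of chromatographic fingerprints: methods and design"
author: "qparfp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-activity modelling of chromatographic fingerprints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qparfp)
```

## The problem

Herbal extracts are complex mixtures; a single marker compound rarely
explains their biological activity. Quantitative pattern-activity
relationship (QPAR) modelling treats the *whole* HPLC-DAD chromatogram of an
extract — the chemical fingerprint, a high-dimensional vector of intensities
over retention time — as the predictor, and a measured bioactivity as the
response. The motivating application is a panel of 72 aqueous *Radix
Astragali* extracts (3 batches of 24, prepared under varying reflux time and
solvent volume) whose bioactivity is the % change of CD80 expression on
THP-1-derived dendritic cells relative to an untreated control. Two models
are compared throughout: plain partial least squares (PLS) on every grid
point, and PLS refit on the support chosen by an elastic net (EN-PLS).

The package implements the full workflow — simulation, preprocessing,
similarity diagnostics, sample splitting, modelling, validation metrics and
region-perturbation sensitivity analysis — as composable functions, plus
`runQPAR()` which chains them from a single configuration.

## The activity scale

Per-sample activities appear in two equivalent conventions: the delta scale
(`+8.33` means an 8.33% increase of CD80 expression over control) and the
`100 + delta` scale used in test-set prediction tables (`105.95` means
`+5.95`). The generator emits the `100 + delta` scale (offset configurable
via `activityOffset`); the packaged reference tables keep each source's
native convention, documented in `?referenceActivities` and
`?referenceTestSet`. All error metrics are scale-agnostic.

## Synthetic data generator

Raw chromatograms for the reference panel were never deposited, so the
package ships a generator that reproduces the *statistical structure* the
analysis relies on, with known ground truth:

* **Signal**: a library of Gaussian peaks (default 40 peaks over a 0–70 min
  run sampled at 0.05 min, 1401 grid points, mirroring a 70-minute gradient
  programme at desk-scale resolution; the instrument-resolution grid of
  ~10000 points is configurable but not the default). Chromatographic
  tailing is omitted: the models consume intensity patterns, never peak
  shapes.
* **Composition variation**: per-batch and per-sample log-normal abundance
  multipliers per peak (`batchEffectSd = 0.25`, `withinBatchSd = 0.25`).
  The batch multiplier emulates raw-material differences between batches;
  with these defaults within-batch similarity indices fall in the low-90s
  to high-90s % and between-batch references agree at the 90–99% level, the
  regime reported for real multi-batch extract panels.
* **Nuisance**: a smooth random quadratic baseline (amplitude 15 a.u.),
  a global retention-time jitter per sample (sd 0.05 min), and iid detector
  noise (sd 1 a.u.).
* **Truth**: activity = `100 + sum(beta * cleanSignal) + noise`
  (`activityNoiseSd = 5`). The default `beta` marks five active peaks spread
  over the run, normalized so their nominal contributions are +20, −16,
  +26, +13 and −33 activity %; the batch multipliers then induce batch-mean
  activity shifts of order 10%, and the within-sample variation plus the 5%
  measurement noise give within-batch spreads of order 10% — both matching
  the reference panel's summary statistics.

All randomness derives from one seed in a documented draw order, so panels
are bit-reproducible. What the generator does **not** emulate: multi-
wavelength DAD cubes (a single detection channel is emitted; the source
panel recorded five wavelengths without stating which fed the model),
correlated (1/f) detector drift, peak-shape distortions, and nonlinear
detector response. Passing tests on synthetic panels therefore validate the
estimators and the pipeline logic, not instrument-specific preprocessing
performance on real data.

## Preprocessing

The reference workflow used proprietary fingerprint software for baseline
correction and peak alignment; the package substitutes fully specified
standard algorithms and logs every step with its parameters:

* **Baseline**: asymmetric least squares — minimize
  `sum(w_i (y_i - z_i)^2) + smoothness * sum((d2 z)_i^2)` with weights
  `asymmetry` above and `1 - asymmetry` below the current estimate
  (defaults `1e5`, `0.01`, 10 reweighting iterations). The smoothness
  default keeps the baseline's bending length (~`smoothness^(1/4)` ≈ 18 grid
  points) well above peak widths. Because the reweighting is discrete and
  the penalty has free ends, the corrected trace is shift-equivariant only
  away from the edges and to about `1e-4` of trace norm — adequate, since
  alignment shifts are a few grid steps.
* **Alignment**: one global integer-step shift per sample, maximizing the
  inner product with the panel median, bounded by `maxShift` (default 0.5
  min); shifted-out edges are zero-filled and ties prefer the smallest
  displacement. Piecewise warping is deliberately out of scope: the source
  workflow states only "baseline correction and peak alignment", and a
  single rigid shift is the simplest method meeting that purpose.
* **Gridding**: linear interpolation onto the common grid; a sample whose
  observed range does not cover the grid is an error (no extrapolation).
* **Normalization**: none by default. Region perturbation interprets
  absolute region intensity as compound quantity; total-area scaling would
  distort that and is available only as an explicit opt-in.

## Similarity and homogeneity diagnostics

The similarity index (SI) of a fingerprint against its batch's pointwise
median reference is the congruence (cosine) coefficient × 100. The source
report never states its SI formula; cosine similarity is the standard
chromatographic choice, yields the reported high-80s-to-99% range on
non-negative traces, and is scale-invariant (a Pearson variant is available
via `method = "pearson"`). Batch summaries use the sample (n−1) standard
deviation. PCA score plots (`pcaScores()`, SVD on the column-centered
matrix) serve as the panel homogeneity check.

## Kennard–Stone splitting

`kennardStone()` selects the calibration set by max–min Euclidean distance:
the seed pair is the most distant pair; every subsequent pick maximizes its
minimum distance to the selected set; ties go to the lowest original index,
making the split deterministic and permutation-robust. The training
fraction default is 2/3 with round-half-up (72 samples → 48). The split is
computed on the preprocessed matrix (the source does not say whether raw or
preprocessed intensities were used; this choice is recorded in the split
artefact). Both models always share one split.

## PLS core

`fitPLS()` implements NIPALS for a univariate response, where the weight
vector of each round is exactly the normalized deflated covariance
`X_d' y_d` — no inner iteration, hence fully deterministic. Data are
mean-centered only: all variables share one unit (absorbance), and the
perturbation analysis needs coefficients on the raw intensity scale;
autoscaling is an opt-in flag and is recorded in the model. Component count
is chosen by leave-one-out cross-validation (`looCV()`), exploiting the
nestedness of NIPALS components (one refit per held-out sample at the
maximum count, truncated to every smaller count); the optimum is the RMSECV
argmin with ties to fewer components. The cap defaults to `min(15, n - 2)`
— deliberately above the 7–8 components reported for the reference data, so
the count is discovered, not imposed.

## Elastic-net selection and EN-PLS

`fitElasticNet()` minimizes
`||y - X b||^2 + lambda1 ||b||_1 + lambda2 ||b||^2` by cyclic coordinate
descent (fixed ascending coordinate order; convergence when a full sweep
moves no coordinate by `tol = 1e-6`; between full sweeps the active set is
polished, which is where nearly all progress happens on collinear
chromatographic designs). This is the *naive* elastic net: no
`(1 + lambda2)` rescaling is applied, because only the support feeds the
downstream PLS refit and the support is invariant to that rescaling.
`fitENPLS()` refits PLS on the selected columns with LOO component
selection, so the final model predicts directly from full-grid
fingerprints.

Two penalty regimes matter, and the distinction is a consequence of leaving
the data unstandardized:

* **Prediction-oriented tuning** (`tuneEN()`): grid search scored by k-fold
  CV RMSE of the downstream EN-PLS fit, folds taken as contiguous blocks of
  the Kennard–Stone order (deterministic), ties to the sparser model. The
  default grids are `lambda1` geometric from the KKT null threshold
  (`lambda1Max()`) down by 10^-3, and `lambda2` in {0.01, 0.1, 1, 10}.
  On raw absorbance scales the column sums of squares are ~10^5–10^6, so
  these conventional `lambda2` values are effectively a pure lasso: good
  for prediction, but the support collapses to isolated representative
  points of each correlated peak block.
* **Selection-oriented penalties** for recovering *which* regions are
  active: `lambda2` must rival the column sums of squares for the grouping
  effect (near-equal coefficients on highly correlated variables) to act.
  The package's documented setting for the default synthetic conditions is
  `lambda1 = 0.01 * lambda1Max`, `lambda2 = 3e5`; under it the support
  recovers ~90% of the truly active grid points on average across replicate
  panels while EN-PLS still beats plain PLS on test RMSEP.

## Validation metrics

`validationReport()` assembles the standard table: R² values are squared
Pearson correlations of predicted vs experimental activities (training and
test); RMSET/RMSECV/RMSEP are root mean squared errors of the training fit,
the LOO cross-validation, and the external test set; per-sample REP is the
plain difference `predicted - actual` and PRESS its square, so
`RMSEP^2 * n = sum(PRESS)` holds exactly; q² is
`1 - sum((pred - act)^2) / sum((act - mean(act))^2)`. Two conventions
deserve a note. First, published QPAR test-set tables print REP as the
plain difference even where a footnote defines a percentage ratio; every
printed cell satisfies the difference convention, so that is the default,
with the ratio variant behind `relative = TRUE`. Second, q² and the squared
correlation R²p answer different questions — on the packaged reference test
set the PLS predictions give R²p ≈ 0.33 but q² ≈ 0.20, because q² also
penalizes bias and scale error; both are reported, and the package never
conflates them.

## Region perturbation

`selectRegions()` partitions a model's full-grid coefficient vector into
maximal same-sign runs (a run is "zero" when `|coef| < 1e-8 * max|coef|`),
keeps runs of at least `minWidth` grid points (default 5), and ranks them
by the absolute aggregate coefficient (zero runs by width). The published
region table's "correlation coefficient" column is interpreted as this
aggregate regression coefficient — it is the only quantity that propagates
linearly into the printed dose-response outputs; the region boundaries
themselves are data-driven here because the original 13 intervals are
unrecoverable. `perturbAndPredict()` scales a region of the panel-mean
fingerprint by `1 + fractionalIncrease` (default scales +50%, +100%,
+200%) and reports the change in predicted activity. Because the models
are affine, deltas are exactly linear in the scale (the +200% delta is
exactly 4× the +50% delta), additive over disjoint regions, and exactly
zero for zero-coefficient regions — these identities are asserted in the
test suite rather than any specific numeric cell, which would require the
original chromatograms. Note that zero-coefficient runs exist only where
whole grid stretches carry no signal variance; on densely noisy
fingerprints request `nZero = 0`.

## Numerical and degenerate-input policy

Zero-variance responses, empty selections, out-of-range component counts,
uncovered interpolation grids and malformed input files raise immediate,
named errors; elastic-net non-convergence is a warning carried in the
result, not a failure. NIPALS stops early (with a warning) if the deflated
covariance vanishes before the requested component count. All estimators
are deterministic given their inputs; the only randomness in the package is
the generator's single seeded stream.

## Problem sizes used in the shipped checks

The test suite exercises two scales, chosen to keep the default run fast
while preserving structure: a small panel (12 peaks, 0–20 min at 0.1 min =
201 variables, 3×8 samples) for unit and pipeline tests, and the
study-scale design (40 peaks, 1401 variables, 3×24 samples, 48/24 split)
for the similarity-range, split-structure, parameter-recovery and
perturbation checks; the recovery study uses 20 replicate panels. The
acceptance script reruns the same study-scale analyses and additionally
recomputes every desk-scale statistic of the packaged reference tables.

## Known limitations

* Exact reproduction of the reference panel's fitted models (variable
  counts, component numbers, training-fit statistics, region coefficients)
  is impossible without the original chromatograms; the package instead
  validates every estimator against closed forms, brute-force oracles and
  synthetic ground truth, and reproduces all desk-scale published
  statistics exactly.
* The single-shift alignment cannot correct nonlinear retention drift;
  correlation-optimized warping is out of scope.
* The elastic net is solved at fixed penalties per fit (no path
  algorithm); tuning is a plain grid search.
* The similarity index formula of the original software is unknown; cosine
  congruence is a documented substitute.
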