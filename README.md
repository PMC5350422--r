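# qparfp — quantitative pattern-activity relationships for chromatographic fingerprints

`qparfp` models the bioactivity of complex herbal extracts from their whole
HPLC fingerprints. Instead of quantifying one marker compound, the entire
chromatogram — intensities over retention time, ~10³–10⁴ variables — is the
predictor **X**, and a measured bioactivity (here the % change of CD80
expression on THP-1-derived dendritic cells versus an untreated control) is
the response **y**. The package is written for chemometricians and
herbal-quality-control researchers who want a fully reproducible, tested
version of this workflow:

1. **Synthetic panels** — a generator for multi-batch fingerprint panels
   (Gaussian peak libraries, batch/sample abundance effects, baseline,
   retention jitter, detector noise) with a known sparse linear
   fingerprint→activity truth, emulating a 3-batch × 24-extract design.
2. **Preprocessing** — asymmetric-least-squares baseline correction, global
   integer-shift alignment to the panel median, linear gridding.
3. **Diagnostics** — similarity index (cosine congruence × 100) against
   batch median references; PCA homogeneity scores.
4. **Splitting** — deterministic Kennard–Stone max–min selection
   (two-thirds training by default: 72 → 48/24).
5. **Models** — NIPALS PLS with leave-one-out component selection
   (`fitPLS()`, `looCV()`), and EN-PLS: elastic-net variable selection
   (cyclic coordinate descent minimizing
   `‖y − Xβ‖² + λ₁‖β‖₁ + λ₂‖β‖²`) followed by a PLS refit on the selected
   support (`fitElasticNet()`, `tuneEN()`, `fitENPLS()`).
6. **Validation** — R²t/R²p (squared Pearson correlations), RMSET, RMSECV,
   RMSEP, q² = 1 − Σ(ŷ−y)²/Σ(y−ȳ)², and per-sample REP/PRESS tables.
7. **Region perturbation** — partition a model's coefficient vector into
   positive / negative / zero regions, scale each region of the mean
   fingerprint by +50/100/200%, and report the predicted activity change:
   a linear-model sensitivity analysis locating bioactivity-related
   chromatogram regions.

The methods vignette (`vignettes/qpar-methods.Rmd`) documents the model
assumptions, parameter defaults and design decisions.

## Worked example

Simulate a study-scale panel (3 batches × 24 extracts, 1401 grid points),
preprocess, inspect similarity, split, and fit both models:

```r
library(qparfp)
lib   <- generatePeakLibrary(40, c(0, 70), 0.05, seed = 11)
panel <- simulatePanel(lib, generationConfig(seed = 42))
fps   <- preprocessPanel(panel$chromatograms, activities = panel$activities)
fps
#> FingerprintSet: 72 samples x 1401 grid points
#>   rt grid: 0.00-70.00 min, step 0.05
#>   batches: batchA, batchB, batchC
#>   preprocessing steps: baseline_als -> build_matrix -> align_to_median

groupSimilarity(fps)$batchA
#> SimilarityReport [batchA]: n = 24, SI % mean 97.8 (sd 1.3), range 93.6-99.0

split <- kennardStone(fps, trainSizeFromRatio(72))   # 48 train / 24 test
X  <- fingerprintMatrix(fps); y <- activities(fps)
tr <- trainIndices(split);    te <- testIndices(split)

pls <- fitPLSCV(X[tr, ], y[tr], grid = rtGrid(fps))
validationReport(pls$model, X[tr, ], y[tr], X[te, ], y[te],
                 rmsecv = unname(pls$rmsecv[pls$optimum]))
#> ValidationReport
#>   training: R2t = 0.924, RMSET = 3.195, RMSECV = 8.733
#>   test:     R2p = 0.656, RMSEP = 7.845, q2 = 0.656
#>   model:    11 components, 1401 variables
```

The within-batch similarity (mean 97.8%, all ≥ 93%) mirrors the
homogeneity seen in real multi-batch extract panels, and the plain-PLS
model predicts the held-out third of the panel with RMSEP 7.8 activity %.
EN-PLS with prediction-tuned penalties improves on that while using a
fraction of the variables:

```r
tune <- tuneEN(X[tr, ], y[tr],
               lambda1Grid = defaultENGrids(X[tr, ], y[tr], nLambda1 = 10)$lambda1,
               lambda2Grid = c(0.1, 1, 10), folds = 5)
en <- fitENPLS(X[tr, ], y[tr], tune$lambda1, tune$lambda2, grid = rtGrid(fps))
validationReport(en$model, X[tr, ], y[tr], X[te, ], y[te],
                 rmsecv = unname(en$rmsecv[en$model@nComponents]))
#> ValidationReport
#>   training: R2t = 0.865, RMSET = 4.262, RMSECV = 6.330
#>   test:     R2p = 0.715, RMSEP = 7.246, q2 = 0.706
#>   model:    11 components, 16 variables
```

For locating *which* chromatogram regions drive the activity, use the
selection-oriented penalties (large λ₂ for the grouping effect; see the
vignette), then perturb regions of the mean fingerprint:

```r
enSel <- fitENPLS(X[tr, ], y[tr],
                  lambda1 = 0.01 * lambda1Max(X[tr, ], y[tr]),
                  lambda2 = 3e5, grid = rtGrid(fps), maxIter = 2e4)
regions <- selectRegions(enSel$model, nPos = 2, nNeg = 2, nZero = 1, minWidth = 5)
perturbationTable(list(ENPLS = enSel$model), meanFingerprint(fps), regions)
#>   region_id category model coefficient delta_50 delta_100 delta_200
#> 1         1 negative ENPLS     -0.0684    -7.83    -15.66     -31.3
#> 2         2 positive ENPLS      0.0740     7.84     15.67      31.3
#> 3         3 negative ENPLS     -0.0730    -9.61    -19.22     -38.4
#> 4         4 positive ENPLS      0.0611     3.95      7.89      15.8
#> 5         5     zero ENPLS      0.0000     0.00      0.00       0.0
```

Doubling a positive region's intensity (`delta_100`) raises the predicted
CD80 change by the region's aggregate coefficient times its intensity;
zero-coefficient regions move nothing, and every delta scales exactly
linearly with the applied increase. On this panel the elastic-net support
recovered 100% of the truly active grid points
(`panel$truth$support`). The one-call pipeline `runQPAR(qparConfig(...))`
chains all of the above and serializes every artefact to CSV/JSON.

The package also ships two published reference tables as plain-text
fixtures — `referenceActivities()` (72 CD80 activities in 3 batches, delta%
scale) and `referenceTestSet()` (24 test-set samples with measured and
predicted activities on the 100+delta scale) — used for exact desk-scale
metric checks.

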