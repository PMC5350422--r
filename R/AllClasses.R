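#' @import methods
#' @importFrom stats approx cor dist median predict quantile rnorm runif rlnorm sd setNames var
#' @importFrom utils head read.csv write.csv
NULL

#' Single-sample chromatogram
#'
#' Holds one sample's retention-time/intensity trace together with its
#' provenance (sample id, batch, extraction conditions).
#'
#' @slot sampleId character scalar.
#' @slot batchId character scalar.
#' @slot rt numeric vector of retention times (minutes), strictly increasing.
#' @slot intensity numeric vector of detector intensities (absorbance units),
#'   same length as `rt`.
#' @slot extraction named list of extraction conditions (e.g. `reflux_hours`,
#'   `solvent_mL`); may be empty.
#'
#' @export
setClass("Chromatogram",
  representation(
    sampleId = "character",
    batchId = "character",
    rt = "numeric",
    intensity = "numeric",
    extraction = "list"
  ),
  prototype(extraction = list())
)

setValidity("Chromatogram", function(object) {
  msg <- character()
  if (length(object@rt) != length(object@intensity))
    msg <- c(msg, "rt and intensity must have equal length")
  if (length(object@rt) > 1 && any(diff(object@rt) <= 0))
    msg <- c(msg, "rt must be strictly increasing")
  if (any(!is.finite(object@intensity)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a Chromatogram
#'
#' @param rt retention-time grid in minutes, strictly increasing.
#' @param intensity intensity trace, same length as `rt`.
#' @param sampleId,batchId identifiers.
#' @param extraction optional named list of extraction conditions.
#' @return A [Chromatogram-class] object.
#' @export
Chromatogram <- function(rt, intensity, sampleId = "sample", batchId = "batch",
                         extraction = list()) {
  new("Chromatogram", sampleId = as.character(sampleId),
      batchId = as.character(batchId), rt = as.numeric(rt),
      intensity = as.numeric(intensity), extraction = extraction)
}

setMethod("show", "Chromatogram", function(object) {
  cat("Chromatogram:", object@sampleId, "(batch", object@batchId, ")\n")
  cat("  ", length(object@rt), "points, rt",
      sprintf("%.2f-%.2f min", min(object@rt), max(object@rt)), "\n")
})

#' Aligned fingerprint panel
#'
#' A `FingerprintSet` stores a panel of chromatographic fingerprints on a
#' shared retention-time grid as a [SummarizedExperiment::SummarizedExperiment]:
#' grid points are rows (rowData column `rt`), samples are columns, and the
#' single assay `"intensity"` holds the traces. Per-sample metadata (batch,
#' extraction conditions, bioactivity) lives in `colData`; the ordered
#' preprocessing log lives in `metadata(x)$preprocessing_log`.
#'
#' @export
#' @import SummarizedExperiment
setClass("FingerprintSet", contains = "SummarizedExperiment")

setValidity("FingerprintSet", function(object) {
  msg <- character()
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  rd <- rowData(object)
  if (!"rt" %in% colnames(rd)) {
    msg <- c(msg, "rowData column 'rt' (retention time) is required")
  } else {
    rt <- rd$rt
    if (length(rt) > 1 && any(diff(rt) <= 0))
      msg <- c(msg, "retention-time grid must be strictly increasing")
  }
  if ("intensity" %in% assayNames(object) &&
      any(!is.finite(assay(object, "intensity"))))
    msg <- c(msg, "intensity matrix must contain no missing values")
  if (!"batch" %in% colnames(colData(object)))
    msg <- c(msg, "colData column 'batch' is required")
  if (length(msg)) msg else TRUE
})

#' Construct a FingerprintSet
#'
#' @param X samples x grid-points intensity matrix (rows are samples, matching
#'   the orientation the regression models use).
#' @param grid shared retention-time grid in minutes, length `ncol(X)`.
#' @param sampleIds character vector of sample identifiers (default: rownames
#'   of `X` or `S1..Sn`).
#' @param batchIds character vector of batch labels, recycled if scalar.
#' @param sampleData optional data.frame of further per-sample columns
#'   (e.g. `activity`, `reflux_hours`).
#' @param log ordered list of preprocessing steps already applied.
#' @return A [FingerprintSet-class].
#' @export
#' @importFrom S4Vectors DataFrame metadata metadata<-
FingerprintSet <- function(X, grid, sampleIds = NULL, batchIds = "batch1",
                           sampleData = NULL, log = list()) {
  X <- as.matrix(X)
  if (ncol(X) != length(grid))
    stop("ncol(X) must equal length(grid)")
  n <- nrow(X)
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(X))) rownames(X) else paste0("S", seq_len(n))
  batchIds <- rep_len(as.character(batchIds), n)
  cd <- S4Vectors::DataFrame(batch = batchIds, row.names = sampleIds)
  if (!is.null(sampleData)) {
    sampleData <- as.data.frame(sampleData)
    for (nm in setdiff(colnames(sampleData), "batch"))
      cd[[nm]] <- sampleData[[nm]]
  }
  se <- SummarizedExperiment(
    assays = list(intensity = t(unname(X))),
    rowData = S4Vectors::DataFrame(rt = as.numeric(grid)),
    colData = cd
  )
  obj <- new("FingerprintSet", se)
  metadata(obj)$preprocessing_log <- log
  obj
}

setMethod("show", "FingerprintSet", function(object) {
  cat("FingerprintSet:", ncol(object), "samples x", nrow(object), "grid points\n")
  rt <- rowData(object)$rt
  cat("  rt grid:", sprintf("%.2f-%.2f min, step %.3g", min(rt), max(rt),
      if (length(rt) > 1) rt[2] - rt[1] else NA_real_), "\n")
  cat("  batches:", paste(unique(colData(object)$batch), collapse = ", "), "\n")
  lg <- metadata(object)$preprocessing_log
  cat("  preprocessing steps:", if (length(lg)) paste(vapply(lg, `[[`, "", "step"),
      collapse = " -> ") else "(none)", "\n")
})

#' Kennard-Stone split
#'
#' @slot trainIndices integer vector in selection order.
#' @slot testIndices integer vector (ascending).
#' @slot distanceMetric name of the distance used.
#' @export
setClass("KSSplit",
  representation(trainIndices = "integer", testIndices = "integer",
                 distanceMetric = "character"))

setValidity("KSSplit", function(object) {
  if (length(intersect(object@trainIndices, object@testIndices)))
    return("train and test indices must be disjoint")
  TRUE
})

setMethod("show", "KSSplit", function(object) {
  cat("KSSplit:", length(object@trainIndices), "train /",
      length(object@testIndices), "test (", object@distanceMetric, "distance )\n")
})

#' Fitted partial least squares model
#'
#' Univariate-response PLS fitted by NIPALS on mean-centered data. Prediction
#' is affine: `yhat = intercept + x[variableSubset] %*% coef`.
#'
#' @slot nComponents number of latent components.
#' @slot xMean,yMean centering applied before fitting.
#' @slot weights p x A weight matrix W.
#' @slot xLoadings p x A loading matrix P.
#' @slot yLoadings length-A response loadings q.
#' @slot coef regression vector on the (possibly restricted) variable set.
#' @slot intercept scalar intercept.
#' @slot variableSubset indices of the model's variables within the full grid.
#' @slot fitted fitted training values.
#' @slot grid retention-time grid of the full fingerprint (may be empty).
#' @export
setClass("PLSModel",
  representation(
    nComponents = "integer",
    xMean = "numeric", yMean = "numeric",
    weights = "matrix", xLoadings = "matrix", yLoadings = "numeric",
    coef = "numeric", intercept = "numeric",
    variableSubset = "integer", fitted = "numeric", grid = "numeric"
  ))

setValidity("PLSModel", function(object) {
  if (length(object@coef) != length(object@variableSubset))
    return("coef length must equal the variable subset size")
  TRUE
})

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel:", object@nComponents, "components,",
      length(object@variableSubset), "variables\n")
})

#' Elastic-net selection result
#'
#' Coefficients of the penalized least-squares problem
#' `||y - X b||^2 + lambda1 * ||b||_1 + lambda2 * ||b||^2` (naive elastic net,
#' data mean-centered internally), fitted by cyclic coordinate descent.
#'
#' @slot lambda1 L1 penalty weight.
#' @slot lambda2 L2 penalty weight.
#' @slot beta full-length coefficient vector.
#' @slot support indices with nonzero beta.
#' @slot nSelected number of selected variables.
#' @slot iterations coordinate-descent sweeps used.
#' @slot converged whether the tolerance was reached.
#' @slot maxChange final maximum coordinate change.
#' @export
setClass("ENSelection",
  representation(
    lambda1 = "numeric", lambda2 = "numeric",
    beta = "numeric", support = "integer", nSelected = "integer",
    iterations = "integer", converged = "logical", maxChange = "numeric"
  ))

setValidity("ENSelection", function(object) {
  if (!identical(object@support, which(object@beta != 0)))
    return("support must equal the nonzero indices of beta")
  if (object@nSelected != length(object@support))
    return("nSelected must equal |support|")
  TRUE
})

setMethod("show", "ENSelection", function(object) {
  cat("ENSelection:", object@nSelected, "of", length(object@beta),
      "variables selected (lambda1 =", object@lambda1,
      ", lambda2 =", object@lambda2, ")\n")
  if (!object@converged)
    cat("  warning: coordinate descent did not reach tolerance\n")
})

#' Within-group similarity report
#'
#' @slot groupLabel batch label.
#' @slot reference median reference fingerprint of the group.
#' @slot si named numeric vector of per-sample similarity indices (%).
#' @slot summary list with `mean`, `sd`, `min`, `max` of `si` (`sd` is `NA`
#'   for groups of fewer than 2 samples).
#' @export
setClass("SimilarityReport",
  representation(groupLabel = "character", reference = "numeric",
                 si = "numeric", summary = "list"))

setMethod("show", "SimilarityReport", function(object) {
  s <- object@summary
  cat(sprintf("SimilarityReport [%s]: n = %d, SI %% mean %.1f (sd %.1f), range %.1f-%.1f\n",
              object@groupLabel, length(object@si), s$mean,
              if (is.na(s$sd)) NA_real_ else s$sd, s$min, s$max))
})

#' Model validation report
#'
#' The standard QPAR metric set: training and test squared correlations,
#' RMSET / RMSECV / RMSEP, the cross-validated determination coefficient q2,
#' and the per-sample test-set table (actual, predicted, REP, PRESS).
#'
#' @slot r2Train squared Pearson correlation, fitted vs experimental (training).
#' @slot rmset training root mean squared error.
#' @slot rmsecv leave-one-out cross-validation RMSE (NA if not computed).
#' @slot nComponents,nVariables model size.
#' @slot r2Test squared Pearson correlation, predicted vs experimental (test).
#' @slot rmsep test-set root mean squared error.
#' @slot q2 `1 - sum((pred - act)^2) / sum((act - mean(act))^2)` on the test set.
#' @slot perSample data.frame with columns actual, predicted, rep, press.
#' @export
setClass("ValidationReport",
  representation(
    r2Train = "numeric", rmset = "numeric", rmsecv = "numeric",
    nComponents = "integer", nVariables = "integer",
    r2Test = "numeric", rmsep = "numeric", q2 = "numeric",
    perSample = "data.frame"
  ))

setValidity("ValidationReport", function(object) {
  ps <- object@perSample
  if (nrow(ps)) {
    if (max(abs(ps$press - ps$rep^2)) > 1e-8)
      return("press must equal rep^2")
    if (abs(object@rmsep - sqrt(mean(ps$press))) > 1e-8 * (1 + object@rmsep))
      return("rmsep must equal sqrt(mean(press))")
  }
  TRUE
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport\n")
  cat(sprintf("  training: R2t = %.3f, RMSET = %.3f, RMSECV = %s\n",
              object@r2Train, object@rmset,
              if (is.na(object@rmsecv)) "NA" else sprintf("%.3f", object@rmsecv)))
  cat(sprintf("  test:     R2p = %.3f, RMSEP = %.3f, q2 = %.3f\n",
              object@r2Test, object@rmsep, object@q2))
  cat(sprintf("  model:    %d components, %d variables\n",
              object@nComponents, object@nVariables))
})

#' Synthetic peak library
#'
#' Gaussian peak shapes used by the fingerprint generator: per-peak center
#' (minutes), width (Gaussian sd, minutes) and base height (absorbance units),
#' plus the retention-time range and grid step.
#'
#' @slot peaks data.frame with columns `center`, `width_sd`, `base_height`,
#'   sorted by center.
#' @slot rtRange numeric length-2 (min, max) in minutes.
#' @slot gridStep grid step in minutes.
#' @export
setClass("PeakLibrary",
  representation(peaks = "data.frame", rtRange = "numeric", gridStep = "numeric"))

setValidity("PeakLibrary", function(object) {
  p <- object@peaks
  msg <- character()
  if (!all(c("center", "width_sd", "base_height") %in% colnames(p)))
    msg <- c(msg, "peaks needs columns center, width_sd, base_height")
  else {
    if (any(p$center <= object@rtRange[1]) || any(p$center >= object@rtRange[2]))
      msg <- c(msg, "all peak centers must lie strictly inside rtRange")
    if (any(p$width_sd <= 0)) msg <- c(msg, "peak widths must be > 0")
    if (any(p$base_height < 0)) msg <- c(msg, "peak heights must be >= 0")
    if (is.unsorted(p$center)) msg <- c(msg, "peaks must be sorted by center")
  }
  if (object@gridStep <= 0) msg <- c(msg, "gridStep must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PeakLibrary", function(object) {
  cat("PeakLibrary:", nrow(object@peaks), "Gaussian peaks on",
      sprintf("%g-%g min (step %g)\n", object@rtRange[1], object@rtRange[2],
              object@gridStep))
})
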