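#' Accessors for qparfp objects
#'
#' Small accessor generics so user code never touches slots directly:
#' `rtGrid()` returns the shared retention-time grid; `fingerprintMatrix()`
#' the samples x points intensity matrix; `sampleIds()`, `batchIds()` and
#' `activities()` per-sample metadata; `preprocessingLog()` the ordered list
#' of applied preprocessing steps; `trainIndices()` / `testIndices()` the two
#' halves of a [KSSplit-class]; `coefVector()` a model's regression vector on
#' the full fingerprint grid; `supportIndices()` an elastic-net support;
#' `similarityIndices()` the per-sample SI values of a report.
#'
#' @param x an object of the documented class.
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rtGrid", function(x) standardGeneric("rtGrid"))

#' @rdname accessors
#' @export
setMethod("rtGrid", "FingerprintSet", function(x) rowData(x)$rt)

#' @rdname accessors
#' @export
setGeneric("fingerprintMatrix", function(x) standardGeneric("fingerprintMatrix"))

#' @rdname accessors
#' @export
setMethod("fingerprintMatrix", "FingerprintSet", function(x) {
  m <- t(assay(x, "intensity"))
  rownames(m) <- colnames(x)
  m
})

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "FingerprintSet", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("batchIds", function(x) standardGeneric("batchIds"))

#' @rdname accessors
#' @export
setMethod("batchIds", "FingerprintSet", function(x) colData(x)$batch)

#' @rdname accessors
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))

#' @rdname accessors
#' @export
setMethod("activities", "FingerprintSet", function(x) {
  if (!"activity" %in% colnames(colData(x))) return(NULL)
  setNames(colData(x)$activity, colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("preprocessingLog", function(x) standardGeneric("preprocessingLog"))

#' @rdname accessors
#' @export
setMethod("preprocessingLog", "FingerprintSet",
          function(x) metadata(x)$preprocessing_log)

#' @rdname accessors
#' @export
setGeneric("trainIndices", function(x) standardGeneric("trainIndices"))

#' @rdname accessors
#' @export
setMethod("trainIndices", "KSSplit", function(x) x@trainIndices)

#' @rdname accessors
#' @export
setGeneric("testIndices", function(x) standardGeneric("testIndices"))

#' @rdname accessors
#' @export
setMethod("testIndices", "KSSplit", function(x) x@testIndices)

#' @rdname accessors
#' @export
setGeneric("coefVector", function(x, ...) standardGeneric("coefVector"))

#' Regression vector of a PLS model
#'
#' @param x a [PLSModel-class].
#' @param full if `TRUE` (default) return the coefficient vector expanded to
#'   the full fingerprint grid (zeros outside `variableSubset`); if `FALSE`
#'   return only the subset coefficients.
#' @param p full grid length; defaults to `max(variableSubset)` when the model
#'   carries no grid.
#' @param ... unused.
#' @export
setMethod("coefVector", "PLSModel", function(x, full = TRUE, p = NULL, ...) {
  if (!full) return(x@coef)
  if (is.null(p)) p <- if (length(x@grid)) length(x@grid) else max(x@variableSubset)
  b <- numeric(p)
  b[x@variableSubset] <- x@coef
  b
})

#' @rdname accessors
#' @export
setMethod("coefVector", "ENSelection", function(x, ...) x@beta)

#' @rdname accessors
#' @export
setGeneric("supportIndices", function(x) standardGeneric("supportIndices"))

#' @rdname accessors
#' @export
setMethod("supportIndices", "ENSelection", function(x) x@support)

#' @rdname accessors
#' @export
setGeneric("similarityIndices", function(x) standardGeneric("similarityIndices"))

#' @rdname accessors
#' @export
setMethod("similarityIndices", "SimilarityReport", function(x) x@si)
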