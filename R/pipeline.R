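#' End-to-end QPAR run configuration
#'
#' Bundles every stage's parameters. Exactly one of `generation` (a
#' [generationConfig()], simulated input) or `inputFiles` (named list with
#' `matrix`, `metadata`, `activities` paths) must be supplied.
#'
#' @param generation a [generationConfig()] or `NULL`.
#' @param inputFiles named list of file paths or `NULL`.
#' @param library a [PeakLibrary-class] for simulated input (default:
#'   40 peaks on 0-70 min, step 0.05, seeded from `seed`).
#' @param trainRatio training fraction for the Kennard-Stone split
#'   (default 2/3).
#' @param maxComponents PLS component cap (default `min(15, n - 2)` at fit
#'   time).
#' @param lambda1Grid,lambda2Grid elastic-net tuning grids (`NULL` =
#'   defaults of [tuneEN()]).
#' @param folds tuning folds (default 5).
#' @param scales perturbation fractional increases (default `c(0.5, 1, 2)`).
#' @param nPos,nNeg,nZero,minWidth region-selection parameters (defaults
#'   6/5/2 regions, width >= 5 points).
#' @param preprocessing named list of [preprocessPanel()] arguments.
#' @param seed integer seed (also seeds the default library and generation
#'   config if they carry none).
#' @return list of class `"QPARConfig"`.
#' @export
qparConfig <- function(generation = NULL, inputFiles = NULL, library = NULL,
                       trainRatio = 2 / 3, maxComponents = NULL,
                       lambda1Grid = NULL, lambda2Grid = NULL, folds = 5,
                       scales = c(0.5, 1, 2), nPos = 6, nNeg = 5, nZero = 2,
                       minWidth = 5, preprocessing = list(), seed = 1) {
  if (is.null(generation) && is.null(inputFiles))
    stop("config error: supply either a generation config or input files")
  if (!is.null(generation) && !is.null(inputFiles))
    stop("config error: generation config and input files are exclusive")
  if (trainRatio <= 0 || trainRatio >= 1)
    stop("config error: trainRatio must lie in (0, 1)")
  structure(list(
    generation = generation, inputFiles = inputFiles, library = library,
    trainRatio = trainRatio, maxComponents = maxComponents,
    lambda1Grid = lambda1Grid, lambda2Grid = lambda2Grid, folds = folds,
    scales = scales, nPos = nPos, nNeg = nNeg, nZero = nZero,
    minWidth = minWidth, preprocessing = preprocessing,
    seed = as.integer(seed)), class = "QPARConfig")
}

#' Run the full QPAR pipeline
#'
#' simulate (or read) -> preprocess -> similarity -> Kennard-Stone split ->
#' plain PLS and EN-PLS (both on the same split) -> validation reports ->
#' region perturbation. Deterministic: rerunning with an identical config
#' reproduces every artefact.
#'
#' @param config a [qparConfig()].
#' @param outputDir optional directory; when given, every artefact is
#'   written there (CSV/JSON).
#' @param verbose print per-stage progress (default `FALSE`).
#' @return list of class `"QPARBundle"`: `fingerprints`, `similarity`,
#'   `betweenBatch`, `split`, `pls` (list: model, report, rmsecvCurve),
#'   `enpls` (list: selection, model, report, tuning), `regions`,
#'   `perturbation`, `truth` (for simulated input), `config`.
#' @export
runQPAR <- function(config, outputDir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "QPARConfig"))
  say <- function(...) if (verbose) message(...)

  # --- data stage ---------------------------------------------------------
  truth <- NULL
  if (!is.null(config$generation)) {
    say("stage simulate")
    lib <- config$library
    if (is.null(lib))
      lib <- generatePeakLibrary(40, c(0, 70), 0.05, seed = config$seed)
    panel <- simulatePanel(lib, config$generation)
    truth <- panel$truth
    say("stage preprocess")
    fps <- do.call(preprocessPanel,
                   c(list(chroms = panel$chromatograms,
                          activities = panel$activities),
                     config$preprocessing))
  } else {
    say("stage read")
    fps <- readPanel(config$inputFiles$matrix, config$inputFiles$metadata,
                     config$inputFiles$activities)
  }
  y <- activities(fps)
  if (is.null(y)) stop("data error: no activities available for modelling")
  X <- fingerprintMatrix(fps)
  grid <- rtGrid(fps)

  say("stage similarity")
  sim <- groupSimilarity(fps)
  between <- betweenBatchSimilarity(fps)

  say("stage split")
  nTrain <- trainSizeFromRatio(nrow(X), config$trainRatio)
  split <- kennardStone(X, nTrain)
  tr <- trainIndices(split); te <- testIndices(split)

  say("stage fit PLS")
  maxA <- if (is.null(config$maxComponents))
    min(15L, length(tr) - 2L) else config$maxComponents
  plsFit <- fitPLSCV(X[tr, , drop = FALSE], y[tr], maxComponents = maxA,
                     grid = grid)
  plsReport <- validationReport(plsFit$model, X[tr, , drop = FALSE], y[tr],
                                X[te, , drop = FALSE], y[te],
                                rmsecv = unname(plsFit$rmsecv[plsFit$optimum]))

  say("stage tune + fit EN-PLS")
  tune <- tuneEN(X[tr, , drop = FALSE], y[tr],
                 lambda1Grid = config$lambda1Grid,
                 lambda2Grid = config$lambda2Grid, folds = config$folds,
                 maxComponents = maxA)
  enFit <- fitENPLS(X[tr, , drop = FALSE], y[tr], tune$lambda1,
                    tune$lambda2, maxComponents = maxA, grid = grid)
  enReport <- validationReport(enFit$model, X[tr, , drop = FALSE], y[tr],
                               X[te, , drop = FALSE], y[te],
                               rmsecv = unname(enFit$rmsecv[enFit$model@nComponents]))

  say("stage perturbation")
  base <- meanFingerprint(fps)
  # zero-coefficient regions exist only where whole grid stretches carry no
  # signal variance at all (e.g. detector-quiet segments); on dense noisy
  # fingerprints request nZero = 0
  regions <- selectRegions(plsFit$model, nPos = config$nPos,
                           nNeg = config$nNeg, nZero = config$nZero,
                           minWidth = config$minWidth)
  pert <- perturbationTable(list(PLS = plsFit$model, ENPLS = enFit$model),
                            base, regions, config$scales)

  bundle <- structure(list(
    fingerprints = fps, similarity = sim, betweenBatch = between,
    split = split,
    pls = list(model = plsFit$model, report = plsReport,
               rmsecvCurve = plsFit$rmsecv),
    enpls = list(selection = enFit$selection, model = enFit$model,
                 report = enReport, tuning = tune),
    regions = regions, perturbation = pert, truth = truth,
    config = config), class = "QPARBundle")

  if (!is.null(outputDir)) writeBundle(bundle, outputDir)
  bundle
}

#' Write all artefacts of a QPAR run
#'
#' Serializes the bundle to plain text: fingerprint matrix CSV, similarity
#' CSV + JSON summary, split JSON, model JSONs, validation reports
#' (JSON + per-sample CSV), regions JSON and perturbation CSV.
#'
#' @param bundle a `"QPARBundle"` from [runQPAR()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
writeBundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fps <- bundle$fingerprints
  writeFingerprintCSV(fps, file = file.path(dir, "fingerprints.csv"))
  jsonlite::write_json(
    list(log = preprocessingLog(fps)),
    file.path(dir, "preprocessing_log.json"), auto_unbox = TRUE, digits = NA)
  si <- do.call(rbind, lapply(bundle$similarity, function(r)
    data.frame(sample_id = names(r@si), batch = r@groupLabel,
               si = unname(r@si))))
  write.csv(si, file.path(dir, "similarity.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(bundle$similarity, function(r) r@summary),
    file.path(dir, "similarity_summary.json"), auto_unbox = TRUE,
    digits = NA, na = "null")
  writeSplitJSON(bundle$split, file.path(dir, "split.json"))
  writeModelJSON(bundle$pls$model, file.path(dir, "pls_model.json"))
  writeModelJSON(bundle$enpls$model, file.path(dir, "enpls_model.json"))
  writeSelectionJSON(bundle$enpls$selection,
                     file.path(dir, "en_selection.json"))
  writeReport(bundle$pls$report, file.path(dir, "pls_report.json"),
              file.path(dir, "pls_testset.csv"))
  writeReport(bundle$enpls$report, file.path(dir, "enpls_report.json"),
              file.path(dir, "enpls_testset.csv"))
  jsonlite::write_json(bundle$regions, file.path(dir, "regions.json"),
                       digits = NA, na = "null")
  write.csv(bundle$perturbation, file.path(dir, "perturbation.csv"),
            row.names = FALSE)
  invisible(dir)
}
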