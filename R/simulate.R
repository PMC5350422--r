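#' Generate a random Gaussian peak library
#'
#' Draws a set of Gaussian peak shapes on a retention-time axis: centers
#' uniform strictly inside `rtRange`, widths uniform on 0.08-0.40 min
#' (typical HPLC peak sd at mid-gradient), base heights log-normal
#' (meanlog `log(150)`, sdlog 0.7 absorbance units). Peaks are returned
#' sorted by center.
#'
#' @param nPeaks number of peaks (>= 1).
#' @param rtRange numeric length-2 retention-time window, minutes.
#' @param gridStep sampling step in minutes (> 0).
#' @param seed integer seed; the same seed always yields the same library.
#' @return A [PeakLibrary-class].
#' @examples
#' lib <- generatePeakLibrary(10, c(0, 70), 0.05, seed = 1)
#' lib
#' @export
generatePeakLibrary <- function(nPeaks, rtRange = c(0, 70), gridStep = 0.05,
                                seed = 1) {
  if (length(nPeaks) != 1 || nPeaks < 1 || nPeaks != round(nPeaks))
    stop("nPeaks must be a positive integer")
  if (length(rtRange) != 2 || rtRange[1] >= rtRange[2])
    stop("rtRange must be an ordered (min, max) pair")
  if (gridStep <= 0) stop("gridStep must be > 0")
  set.seed(as.integer(seed))
  span <- diff(rtRange)
  margin <- 0.02 * span
  centers <- sort(runif(nPeaks, rtRange[1] + margin, rtRange[2] - margin))
  widths <- runif(nPeaks, 0.08, 0.40)
  heights <- rlnorm(nPeaks, meanlog = log(150), sdlog = 0.7)
  new("PeakLibrary",
      peaks = data.frame(center = centers, width_sd = widths,
                         base_height = heights),
      rtRange = as.numeric(rtRange), gridStep = gridStep)
}

#' Configuration for the synthetic fingerprint generator
#'
#' Defaults reproduce the design of the study panel the package targets:
#' 3 batches of 24 aqueous extracts (72 samples), a 0-70 min chromatogram
#' sampled at the library's grid step, batch-to-batch composition shifts,
#' and a sparse linear fingerprint-to-activity relationship on the
#' 100 + delta% activity scale.
#'
#' Noise knobs (all >= 0):
#' * `batchEffectSd` — sdlog of the per-batch log-normal abundance multiplier
#'   applied per peak (shared by all samples of a batch).
#' * `withinBatchSd` — sdlog of the per-sample per-peak log-normal multiplier.
#' * `baselineAmplitude` — scale (absorbance units) of a smooth random
#'   quadratic baseline drift added per sample.
#' * `rtJitterSd` — sd (minutes) of a per-sample global retention-time shift.
#' * `noiseSd` — sd of iid detector noise added pointwise.
#' * `activityNoiseSd` — sd of the activity measurement error (activity %).
#'
#' `trueBeta` is the sparse coefficient vector linking the clean peak signal
#' to activity; `NULL` means the documented default pattern is derived from
#' the peak library at simulation time (five active peaks spread over the
#' run, alternating sign; see [defaultTrueBeta()]).
#'
#' @param nBatches,nPerBatch panel design (default 3 x 24).
#' @param batchEffectSd,withinBatchSd,baselineAmplitude,rtJitterSd,noiseSd,activityNoiseSd
#'   noise parameters, see Details.
#' @param trueBeta full-grid coefficient vector or `NULL` for the default.
#' @param activityOffset additive activity offset (default 100, i.e. activity
#'   is reported as 100 + delta%).
#' @param seed integer seed driving all randomness of [simulatePanel()].
#' @return A named list of class `"GenerationConfig"`.
#' @export
generationConfig <- function(nBatches = 3, nPerBatch = 24,
                             batchEffectSd = 0.25, withinBatchSd = 0.25,
                             baselineAmplitude = 15, rtJitterSd = 0.05,
                             noiseSd = 1, trueBeta = NULL,
                             activityNoiseSd = 5, activityOffset = 100,
                             seed = 1) {
  if (nBatches < 1 || nBatches != round(nBatches))
    stop("nBatches must be a positive integer")
  if (nPerBatch < 1 || nPerBatch != round(nPerBatch))
    stop("nPerBatch must be a positive integer")
  sds <- c(batchEffectSd, withinBatchSd, baselineAmplitude, rtJitterSd,
           noiseSd, activityNoiseSd)
  if (any(sds < 0)) stop("all noise parameters must be >= 0")
  structure(list(
    nBatches = as.integer(nBatches), nPerBatch = as.integer(nPerBatch),
    batchEffectSd = batchEffectSd, withinBatchSd = withinBatchSd,
    baselineAmplitude = baselineAmplitude, rtJitterSd = rtJitterSd,
    noiseSd = noiseSd, trueBeta = trueBeta,
    activityNoiseSd = activityNoiseSd, activityOffset = activityOffset,
    seed = as.integer(seed)
  ), class = "GenerationConfig")
}

#' Default sparse truth for a peak library
#'
#' Marks five "active" peaks, evenly spread across the library, as carrying
#' the fingerprint-activity relationship. The coefficient vector is constant
#' over each active peak's core (grid points within one width sd of the peak
#' center) and zero elsewhere. Each region's coefficient is normalized by
#' the region's intensity at base peak heights so that the regions
#' contribute target activity amounts of +20, -16, +26, +13 and -33
#' activity % at nominal abundance: both up- and down-regulating regions
#' exist, the net mean activity shift is small (about +10%), and the
#' multiplicative batch/sample abundance variation then produces
#' batch-mean shifts and within-batch spreads of the order seen in real
#' multi-batch extract panels (roughly 10 activity % each).
#'
#' @param library a [PeakLibrary-class].
#' @param grid the retention-time grid the panel will use.
#' @return list with `beta` (full-grid numeric) and `activePeaks`
#'   (library row indices used).
#' @export
defaultTrueBeta <- function(library, grid) {
  pk <- library@peaks
  nP <- nrow(pk)
  nActive <- min(5L, nP)
  idx <- unique(round(seq(1, nP, length.out = nActive + 2)))[-c(1, nActive + 2)]
  if (length(idx) < nActive)
    idx <- unique(c(idx, seq_len(nP)))[seq_len(nActive)]
  targets <- c(20, -16, 26, 13, -33)[seq_len(nActive)]
  nominal <- gaussian_signal(grid, pk$center, pk$width_sd, pk$base_height)
  beta <- numeric(length(grid))
  for (k in seq_along(idx)) {
    i <- idx[k]
    on <- abs(grid - pk$center[i]) <= pk$width_sd[i]
    beta[on] <- targets[k] / sum(nominal[on])
  }
  list(beta = beta, activePeaks = idx)
}

gaussian_signal <- function(grid, centers, widths, heights, shift = 0) {
  sig <- numeric(length(grid))
  for (k in seq_along(centers))
    sig <- sig + heights[k] *
      exp(-((grid - centers[k] - shift)^2) / (2 * widths[k]^2))
  sig
}

#' Simulate a multi-batch fingerprint panel with bioactivities
#'
#' Generates `nBatches * nPerBatch` chromatograms on the library's common
#' grid plus per-sample bioactivities and a ground-truth record. The signal
#' model per sample is
#' `intensity = sum_k h_k * m_batch,k * m_sample,k * N(rt; center_k + shift, w_k)`
#' plus a smooth random baseline and iid detector noise; the activity model is
#' `activity = activityOffset + sum_j beta_j * signal_j + noise`, where
#' `signal` is the clean (baseline- and noise-free) trace, so that ideal
#' preprocessing recovers the linear relationship exactly.
#'
#' All randomness comes from one generator seeded with `config$seed`, drawn
#' in a fixed order: batch multipliers first (batch by batch), then per
#' sample (in batch-major order) the within-batch multipliers, the
#' retention-time shift, the baseline coefficients, the detector noise and
#' the activity noise. Identical configs therefore give identical panels.
#'
#' Extraction metadata cycles through the crossed design of reflux time
#' (0-4 h) and solvent volume (100-250 mL) used by aqueous pharmacopoeia
#' extractions.
#'
#' @param library a [PeakLibrary-class] (must contain >= 1 peak).
#' @param config a [generationConfig()] list.
#' @return list with elements `chromatograms` (list of
#'   [Chromatogram-class]), `activities` (named numeric), and `truth` (list:
#'   `trueBeta`, `support`, `trueActivities`, `activePeaks`, `config`).
#' @examples
#' lib <- generatePeakLibrary(12, c(0, 20), 0.1, seed = 3)
#' panel <- simulatePanel(lib, generationConfig(nBatches = 2, nPerBatch = 3))
#' length(panel$chromatograms)
#' @export
simulatePanel <- function(library, config = generationConfig()) {
  if (!is(library, "PeakLibrary")) stop("library must be a PeakLibrary")
  if (nrow(library@peaks) == 0) stop("peak library is empty")
  if (!inherits(config, "GenerationConfig"))
    stop("config must come from generationConfig()")
  pk <- library@peaks
  nP <- nrow(pk)
  grid <- seq(library@rtRange[1], library@rtRange[2], by = library@gridStep)
  if (is.null(config$trueBeta)) {
    tb <- defaultTrueBeta(library, grid)
    beta <- tb$beta
    activePeaks <- tb$activePeaks
  } else {
    beta <- config$trueBeta
    if (length(beta) != length(grid))
      stop("trueBeta must have one coefficient per grid point (",
           length(grid), ")")
    activePeaks <- integer()
  }

  set.seed(config$seed)
  nB <- config$nBatches; nS <- config$nPerBatch
  batchMult <- matrix(exp(rnorm(nB * nP, sd = config$batchEffectSd)),
                      nrow = nB, byrow = TRUE)
  design <- expand.grid(reflux_hours = 0:4,
                        solvent_mL = c(100, 150, 200, 250))
  tn <- (grid - min(grid)) / max(diff(range(grid)), .Machine$double.eps)

  chroms <- vector("list", nB * nS)
  acts <- numeric(nB * nS)
  trueActs <- numeric(nB * nS)
  ids <- character(nB * nS)
  i <- 0L
  for (b in seq_len(nB)) {
    batchLab <- paste0("batch", LETTERS[b])
    for (s in seq_len(nS)) {
      i <- i + 1L
      sampMult <- exp(rnorm(nP, sd = config$withinBatchSd))
      shift <- rnorm(1, sd = config$rtJitterSd)
      bl <- config$baselineAmplitude *
        (runif(1) + runif(1) * tn + runif(1) * tn^2)
      noise <- rnorm(length(grid), sd = config$noiseSd)
      h <- pk$base_height * batchMult[b, ] * sampMult
      signal <- gaussian_signal(grid, pk$center, pk$width_sd, h, shift)
      trueActs[i] <- config$activityOffset + sum(beta * signal)
      acts[i] <- trueActs[i] + rnorm(1, sd = config$activityNoiseSd)
      d <- design[((s - 1L) %% nrow(design)) + 1L, ]
      ids[i] <- paste0(LETTERS[b], s)
      chroms[[i]] <- Chromatogram(
        rt = grid, intensity = signal + bl + noise,
        sampleId = ids[i], batchId = batchLab,
        extraction = list(reflux_hours = d$reflux_hours,
                          solvent_mL = d$solvent_mL))
    }
  }
  names(acts) <- ids
  names(trueActs) <- ids
  list(
    chromatograms = chroms,
    activities = acts,
    truth = list(trueBeta = beta, support = which(beta != 0),
                 trueActivities = trueActs, activePeaks = activePeaks,
                 config = config)
  )
}

#' Write a simulated panel to plain-text files
#'
#' Writes the grid (one column, minutes), the samples x points intensity
#' matrix (CSV, header = grid), per-sample metadata, activities, and the
#' ground truth as JSON.
#'
#' @param panel output of [simulatePanel()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
writePanel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ch <- panel$chromatograms
  grid <- ch[[1]]@rt
  X <- do.call(rbind, lapply(ch, function(c) c@intensity))
  rownames(X) <- vapply(ch, function(c) c@sampleId, "")
  paths <- c(grid = file.path(dir, "grid.txt"),
             matrix = file.path(dir, "intensity.csv"),
             metadata = file.path(dir, "metadata.csv"),
             activities = file.path(dir, "activities.csv"),
             truth = file.path(dir, "truth.json"))
  writeLines(format(grid, trim = TRUE, scientific = FALSE), paths["grid"])
  writeFingerprintCSV(X, grid, paths["matrix"])
  meta <- data.frame(
    sample_id = rownames(X),
    batch = vapply(ch, function(c) c@batchId, ""),
    reflux_hours = vapply(ch, function(c) c@extraction$reflux_hours, 0),
    solvent_mL = vapply(ch, function(c) c@extraction$solvent_mL, 0))
  write.csv(meta, paths["metadata"], row.names = FALSE)
  write.csv(data.frame(sample_id = names(panel$activities),
                       activity = unname(panel$activities)),
            paths["activities"], row.names = FALSE)
  tr <- panel$truth
  jsonlite::write_json(
    list(beta = tr$trueBeta, support = tr$support,
         seed = tr$config$seed, config = unclass(tr$config)),
    paths["truth"], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
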