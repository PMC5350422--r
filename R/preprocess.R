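#' Asymmetric-least-squares baseline estimate
#'
#' Estimates a smooth baseline under a trace by iteratively reweighted
#' penalized least squares: minimize
#' `sum_i w_i (y_i - z_i)^2 + smoothness * sum_i (d2 z)_i^2`, with weights
#' `asymmetry` for points above the current baseline (peaks) and
#' `1 - asymmetry` for points below. Small `asymmetry` pushes the baseline
#' under the peaks.
#'
#' @param y numeric trace.
#' @param smoothness second-difference penalty weight (default 1e5).
#' @param asymmetry fraction in (0, 1), weight of above-baseline points
#'   (default 0.01).
#' @param maxIter reweighting iterations (default 10).
#' @return numeric baseline, same length as `y`.
#' @export
#' @importFrom Matrix bandSparse Diagonal solve crossprod
alsBaseline <- function(y, smoothness = 1e5, asymmetry = 0.01, maxIter = 10) {
  n <- length(y)
  if (n < 10) stop("need at least 10 points for baseline estimation")
  if (asymmetry <= 0 || asymmetry >= 1)
    stop("asymmetry must lie strictly between 0 and 1")
  if (smoothness <= 0) stop("smoothness must be > 0")
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(maxIter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + smoothness * DtD, w * y))
    w <- ifelse(y > z, asymmetry, 1 - asymmetry)
  }
  z
}

log_entry <- function(step, ...) c(list(step = step), list(...))

#' Baseline-correct a chromatogram
#'
#' Subtracts the asymmetric-least-squares baseline estimate (see
#' [alsBaseline()]) and records the step in the object's provenance.
#'
#' @param chrom a [Chromatogram-class].
#' @param smoothness,asymmetry,maxIter see [alsBaseline()].
#' @return A corrected [Chromatogram-class] on the same grid.
#' @export
correctBaseline <- function(chrom, smoothness = 1e5, asymmetry = 0.01,
                            maxIter = 10) {
  stopifnot(is(chrom, "Chromatogram"))
  z <- alsBaseline(chrom@intensity, smoothness, asymmetry, maxIter)
  out <- chrom
  out@intensity <- chrom@intensity - z
  out
}

best_shift <- function(x, reference, maxSteps) {
  n <- length(x)
  shifts <- seq.int(-maxSteps, maxSteps)
  # visit small |shift| first so ties keep the least displacement
  shifts <- shifts[order(abs(shifts), shifts)]
  best <- shifts[1]; bestScore <- -Inf
  for (s in shifts) {
    shifted <- shift_fill(x, s)
    sc <- sum(shifted * reference)
    if (sc - bestScore > 1e-12 * max(1, abs(sc))) {
      bestScore <- sc; best <- s
    }
  }
  best
}

shift_fill <- function(x, s) {
  n <- length(x)
  out <- numeric(n)
  if (s == 0) return(x)
  if (s > 0) out[(s + 1):n] <- x[1:(n - s)]
  else out[1:(n + s)] <- x[(1 - s):n]
  out
}

#' Align a chromatogram to a reference trace
#'
#' Applies the single integer-step lateral shift within `+-maxShift` minutes
#' that maximizes the inner product with the reference trace; points shifted
#' beyond the grid edge are zero-filled. Ties prefer the smallest absolute
#' shift, so an already aligned trace is returned unchanged.
#'
#' @param chrom a [Chromatogram-class].
#' @param reference numeric trace on the same grid.
#' @param maxShift maximal absolute shift in minutes (>= 0); must not exceed
#'   half the grid span.
#' @return The realigned [Chromatogram-class]. When aligning a whole panel
#'   use [preprocessPanel()], which records each sample's chosen shift in the
#'   preprocessing log.
#' @export
alignToReference <- function(chrom, reference, maxShift) {
  stopifnot(is(chrom, "Chromatogram"))
  if (length(reference) != length(chrom@rt))
    stop("reference must be on the same grid as the chromatogram")
  if (maxShift < 0) stop("maxShift must be >= 0")
  step <- if (length(chrom@rt) > 1) chrom@rt[2] - chrom@rt[1] else 1
  span <- diff(range(chrom@rt))
  if (maxShift > span / 2)
    stop("maxShift exceeds half the grid span")
  maxSteps <- floor(maxShift / step + 1e-9)
  s <- best_shift(chrom@intensity, reference, maxSteps)
  out <- chrom
  out@intensity <- shift_fill(chrom@intensity, s)
  out
}

align_shift <- function(x, reference, maxSteps) {
  s <- best_shift(x, reference, maxSteps)
  list(shift = s, x = shift_fill(x, s))
}

#' Interpolate chromatograms onto a common grid
#'
#' Linearly interpolates each chromatogram onto `targetGrid` and stacks the
#' results into a [FingerprintSet-class] (row order = input order). Each
#' chromatogram's observed retention-time range must cover the target grid;
#' no extrapolation is performed.
#'
#' @param chroms list of [Chromatogram-class].
#' @param targetGrid numeric retention-time grid.
#' @param activities optional named activity vector to attach (names matched
#'   to sample ids).
#' @param log preprocessing log entries to seed the new object with.
#' @return A [FingerprintSet-class].
#' @export
buildMatrix <- function(chroms, targetGrid, activities = NULL, log = list()) {
  if (!length(chroms)) stop("no chromatograms supplied")
  rows <- lapply(chroms, function(c) {
    if (min(c@rt) > min(targetGrid) + 1e-9 ||
        max(c@rt) < max(targetGrid) - 1e-9)
      stop("sample '", c@sampleId, "': grid not covered by observed rt range")
    approx(c@rt, c@intensity, xout = targetGrid)$y
  })
  X <- do.call(rbind, rows)
  ids <- vapply(chroms, function(c) c@sampleId, "")
  batches <- vapply(chroms, function(c) c@batchId, "")
  sd <- data.frame(
    reflux_hours = vapply(chroms, function(c)
      if (is.null(c@extraction$reflux_hours)) NA_real_
      else as.numeric(c@extraction$reflux_hours), 0),
    solvent_mL = vapply(chroms, function(c)
      if (is.null(c@extraction$solvent_mL)) NA_real_
      else as.numeric(c@extraction$solvent_mL), 0))
  if (!is.null(activities)) {
    missing <- setdiff(ids, names(activities))
    if (length(missing))
      stop("no activity value for sample(s): ", paste(missing, collapse = ", "))
    sd$activity <- unname(activities[ids])
  }
  FingerprintSet(X, targetGrid, sampleIds = ids, batchIds = batches,
                 sampleData = sd,
                 log = c(log, list(log_entry("build_matrix",
                                             n_points = length(targetGrid)))))
}

#' Preprocess a panel of chromatograms into a fingerprint matrix
#'
#' The standard pipeline replacing proprietary fingerprint software:
#' per-sample asymmetric-least-squares baseline correction, linear
#' interpolation onto a common grid, and alignment of every trace to the
#' panel median by a single integer-step shift. Intensities are left on the
#' absolute scale by default; `normalize = TRUE` opts into total-area
#' scaling (each trace scaled so its summed intensity equals the panel mean),
#' which changes the meaning of region-perturbation results and is therefore
#' off by default.
#'
#' @param chroms list of [Chromatogram-class].
#' @param targetGrid common grid (default: grid of the first chromatogram).
#' @param smoothness,asymmetry,maxIter baseline parameters, see [alsBaseline()].
#' @param maxShift alignment search half-width in minutes (default 0.5).
#' @param normalize opt-in total-area normalization (default `FALSE`).
#' @param activities optional named activity vector to attach.
#' @return A [FingerprintSet-class] with a complete preprocessing log.
#' @export
preprocessPanel <- function(chroms, targetGrid = NULL, smoothness = 1e5,
                            asymmetry = 0.01, maxIter = 10, maxShift = 0.5,
                            normalize = FALSE, activities = NULL) {
  if (!length(chroms)) stop("no chromatograms supplied")
  if (is.null(targetGrid)) targetGrid <- chroms[[1]]@rt
  corrected <- lapply(chroms, correctBaseline, smoothness = smoothness,
                      asymmetry = asymmetry, maxIter = maxIter)
  fps <- buildMatrix(corrected, targetGrid, activities = activities,
                     log = list(log_entry("baseline_als",
                                          smoothness = smoothness,
                                          asymmetry = asymmetry,
                                          max_iter = maxIter)))
  X <- fingerprintMatrix(fps)
  step <- if (length(targetGrid) > 1) targetGrid[2] - targetGrid[1] else 1
  maxSteps <- floor(maxShift / step + 1e-9)
  reference <- apply(X, 2, median)
  shifts <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    al <- align_shift(X[i, ], reference, maxSteps)
    X[i, ] <- al$x
    shifts[i] <- al$shift
  }
  if (normalize) {
    areas <- rowSums(X)
    X <- X * (mean(areas) / areas)
  }
  lg <- c(preprocessingLog(fps),
          list(log_entry("align_to_median", max_shift_min = maxShift,
                         shifts_steps = shifts)))
  if (normalize)
    lg <- c(lg, list(log_entry("total_area_normalize")))
  sd <- as.data.frame(colData(fps))
  FingerprintSet(X, targetGrid, sampleIds = sampleIds(fps),
                 batchIds = batchIds(fps),
                 sampleData = sd[setdiff(colnames(sd), "batch")],
                 log = lg)
}
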