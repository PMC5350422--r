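#' Mean fingerprint of a panel
#'
#' Column means of the samples x points matrix — the averaged chromatogram
#' that region-perturbation analysis perturbs.
#'
#' @param fps a [FingerprintSet-class] (or plain matrix).
#' @return numeric vector on the panel grid.
#' @export
meanFingerprint <- function(fps) {
  X <- if (is(fps, "FingerprintSet")) fingerprintMatrix(fps) else as.matrix(fps)
  if (!nrow(X)) stop("empty panel")
  colMeans(X)
}

coef_runs <- function(beta, zeroTol) {
  cls <- ifelse(abs(beta) < zeroTol, 0L, ifelse(beta > 0, 1L, -1L))
  r <- rle(cls)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(start = start, end = end, category = r$values,
             width = r$lengths)
}

#' Select coefficient-driven chromatogram regions
#'
#' Partitions the model's full-grid regression vector into maximal runs of
#' same-sign coefficients (a run is "zero" where `|coef|` is below
#' `1e-8 * max|coef|`), keeps runs of at least `minWidth` grid points, and
#' returns the top `nPos` positive and `nNeg` negative runs ranked by the
#' absolute sum of their coefficients, plus the `nZero` widest zero runs.
#' Regions are pairwise disjoint by construction.
#'
#' @param model a fitted [PLSModel-class] (must carry its grid, or pass `p`).
#' @param nPos,nNeg,nZero number of regions per category.
#' @param minWidth minimum region width in grid points (default 5).
#' @param p full grid length if the model has no stored grid.
#' @return data.frame with columns `region_id`, `start`, `end` (1-based,
#'   inclusive), `rt_start`, `rt_end` (minutes, `NA` without a grid),
#'   `category` (`"positive"`, `"negative"`, `"zero"`) and
#'   `aggregate_coefficient`.
#' @export
selectRegions <- function(model, nPos = 6, nNeg = 5, nZero = 2, minWidth = 5,
                          p = NULL) {
  beta <- coefVector(model, full = TRUE, p = p)
  if (all(beta == 0)) stop("no qualifying regions: all coefficients are zero")
  zeroTol <- 1e-8 * max(abs(beta))
  runs <- coef_runs(beta, zeroTol)
  runs <- runs[runs$width >= minWidth, , drop = FALSE]
  runs$aggregate <- vapply(seq_len(nrow(runs)), function(i)
    sum(beta[runs$start[i]:runs$end[i]]), 0)
  pick <- function(cat, nWant) {
    sub <- runs[runs$category == cat, , drop = FALSE]
    if (nrow(sub) < nWant) {
      lbl <- c(`1` = "positive", `-1` = "negative", `0` = "zero")[as.character(cat)]
      stop("insufficient qualifying runs in the ", lbl, " category (",
           nrow(sub), " available, ", nWant, " requested)")
    }
    ord <- if (cat == 0L) order(-sub$width) else order(-abs(sub$aggregate))
    sub[ord[seq_len(nWant)], , drop = FALSE]
  }
  sel <- rbind(pick(1L, nPos), pick(-1L, nNeg), pick(0L, nZero))
  sel <- sel[order(sel$start), , drop = FALSE]
  grid <- model@grid
  data.frame(
    region_id = seq_len(nrow(sel)),
    start = sel$start, end = sel$end,
    rt_start = if (length(grid)) grid[sel$start] else NA_real_,
    rt_end = if (length(grid)) grid[sel$end] else NA_real_,
    category = c(`1` = "positive", `-1` = "negative",
                 `0` = "zero")[as.character(sel$category)],
    aggregate_coefficient = ifelse(abs(sel$aggregate) < zeroTol, 0,
                                   sel$aggregate),
    row.names = NULL)
}

#' Predicted activity change from scaling one region
#'
#' Multiplies the intensities of one region of a base fingerprint by
#' `1 + fractionalIncrease`, re-predicts, and returns the change in
#' predicted activity (delta on the activity % scale). Because the model is
#' affine, the change equals
#' `fractionalIncrease * sum_j(coef_j * base_j)` over the region, so deltas
#' scale exactly linearly with the fractional increase.
#'
#' @param model a fitted [PLSModel-class].
#' @param base full-grid base fingerprint (typically [meanFingerprint()]).
#' @param region one row of [selectRegions()] output (or any list with
#'   `start` and `end` grid indices).
#' @param fractionalIncrease scale factor minus one (0.5 = +50%), >= 0.
#' @return scalar predicted activity change.
#' @export
perturbAndPredict <- function(model, base, region, fractionalIncrease) {
  if (fractionalIncrease < 0) stop("fractionalIncrease must be >= 0")
  s <- region$start; e <- region$end
  if (is.null(s) || is.null(e) || s < 1 || e > length(base) || s > e)
    stop("region indices fall outside the fingerprint grid")
  perturbed <- base
  perturbed[s:e] <- base[s:e] * (1 + fractionalIncrease)
  unname(predict(model, matrix(perturbed, nrow = 1)) -
         predict(model, matrix(base, nrow = 1)))
}

#' Full region x model x scale perturbation table
#'
#' Evaluates [perturbAndPredict()] for every region, every model, and every
#' fractional increase, and reports each model's aggregate regression
#' coefficient over the region alongside. With the default scales
#' `c(0.5, 1, 2)` the columns are the predicted activity changes at +50%,
#' +100% and +200% region intensity.
#'
#' @param models named list of fitted [PLSModel-class] objects sharing one
#'   grid.
#' @param base full-grid base fingerprint.
#' @param regions data.frame from [selectRegions()].
#' @param scales fractional increases (default `c(0.5, 1, 2)`).
#' @return data.frame: `region_id`, `category`, `model`, `coefficient`
#'   (aggregate over the region), and one `delta_<pct>` column per scale.
#' @export
perturbationTable <- function(models, base, regions,
                              scales = c(0.5, 1, 2)) {
  if (is.null(names(models)) || any(names(models) == ""))
    stop("models must be a named list")
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    reg <- regions[r, ]
    for (mn in names(models)) {
      m <- models[[mn]]
      beta <- coefVector(m, full = TRUE, p = length(base))
      row <- data.frame(region_id = reg$region_id, category = reg$category,
                        model = mn,
                        coefficient = sum(beta[reg$start:reg$end]))
      for (s in scales)
        row[[sprintf("delta_%g", 100 * s)]] <-
          perturbAndPredict(m, base, reg, s)
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
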