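#' Kennard-Stone training-set selection
#'
#' Deterministic max-min-distance selection of a representative calibration
#' subset: the first two picks are the pair at maximal Euclidean distance;
#' each further pick maximizes its minimum distance to the already selected
#' samples. Ties are broken by the lowest original index, so the result is
#' invariant to how candidates with equal criterion values are encountered.
#'
#' @param X a [FingerprintSet-class] or a plain samples x variables matrix.
#' @param nTrain number of training samples to select (2..n).
#' @return A [KSSplit-class]; train indices are in selection order.
#' @examples
#' ks <- kennardStone(matrix(c(0, 1, 2, 10)), 2)
#' trainIndices(ks) # the extreme pair
#' @export
kennardStone <- function(X, nTrain) {
  if (is(X, "FingerprintSet")) X <- fingerprintMatrix(X)
  X <- as.matrix(X)
  n <- nrow(X)
  if (nTrain < 2 || nTrain > n)
    stop("nTrain must lie in 2..n_samples")
  D <- as.matrix(dist(X))
  # seed pair: maximal distance, ties -> smallest (i, j)
  best <- c(1L, 2L); bestD <- -Inf
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (D[i, j] > bestD + 1e-12 * max(1, bestD)) {
      bestD <- D[i, j]; best <- c(i, j)
    }
  }
  sel <- best
  candidates <- setdiff(seq_len(n), sel)
  while (length(sel) < nTrain) {
    minD <- apply(D[candidates, sel, drop = FALSE], 1, min)
    pick <- candidates[which.max(minD)] # which.max: first max = lowest index
    sel <- c(sel, pick)
    candidates <- setdiff(candidates, pick)
  }
  new("KSSplit", trainIndices = as.integer(sel),
      testIndices = as.integer(sort(candidates)),
      distanceMetric = "euclidean")
}

#' Train-set size from a split ratio
#'
#' Round-half-up of `ratio * n`, the convention used for "two-thirds"
#' calibration splits (72 samples at 2/3 gives 48).
#'
#' @param n total sample count.
#' @param ratio training fraction in (0, 1), default 2/3.
#' @return integer training-set size.
#' @export
trainSizeFromRatio <- function(n, ratio = 2 / 3) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  as.integer(floor(n * ratio + 0.5))
}

#' Serialize a Kennard-Stone split to JSON
#'
#' @param split a [KSSplit-class].
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeSplitJSON <- function(split, file) {
  jsonlite::write_json(
    list(train = split@trainIndices, test = split@testIndices,
         distance_metric = split@distanceMetric),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
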