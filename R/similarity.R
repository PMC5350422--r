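#' Median reference fingerprint
#'
#' Pointwise median over a selection of panel rows — the reference trace a
#' batch's members are compared against.
#'
#' @param fps a [FingerprintSet-class].
#' @param rows sample indices to take the median over (default: all).
#' @return numeric vector on the panel grid.
#' @export
medianReference <- function(fps, rows = seq_len(ncol(fps))) {
  if (!length(rows)) stop("empty row selection")
  X <- fingerprintMatrix(fps)[rows, , drop = FALSE]
  apply(X, 2, median)
}

#' Similarity index between a fingerprint and a reference
#'
#' The congruence (cosine) coefficient scaled to percent:
#' `100 * (x . ref) / (||x|| ||ref||)`. On non-negative chromatograms this is
#' the common fingerprint similarity measure and lands in the high-80s to
#' high-90s for well-behaved replicate extracts. An all-zero `x` yields 0.
#' `method = "pearson"` substitutes the squared-free Pearson correlation of
#' the traces (times 100) as an opt-in alternative.
#'
#' @param x numeric fingerprint.
#' @param reference numeric reference trace, same length, not all zero.
#' @param method `"cosine"` (default) or `"pearson"`.
#' @return Similarity index in percent (in \[-100, 100\]).
#' @examples
#' similarityIndex(c(1, 0), c(1, 1)) # 70.71
#' @export
similarityIndex <- function(x, reference, method = c("cosine", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(reference))
    stop("x and reference must have equal length")
  nr <- sqrt(sum(reference^2))
  if (nr == 0) stop("reference must not be all zero")
  if (method == "pearson") return(100 * cor(x, reference))
  nx <- sqrt(sum(x^2))
  if (nx == 0) return(0)
  100 * sum(x * reference) / (nx * nr)
}

#' Per-batch similarity reports
#'
#' For each batch: the batch median reference, each member's similarity
#' index against it, and summary statistics (mean, sample sd, min, max).
#' Batches with a single member get `sd = NA`.
#'
#' @param fps a [FingerprintSet-class] with batch labels.
#' @param method passed to [similarityIndex()].
#' @return Named list of [SimilarityReport-class], one per batch.
#' @export
groupSimilarity <- function(fps, method = "cosine") {
  batches <- batchIds(fps)
  if (any(is.na(batches) | batches == ""))
    stop("every sample must carry a batch label")
  X <- fingerprintMatrix(fps)
  out <- lapply(unique(batches), function(b) {
    rows <- which(batches == b)
    ref <- medianReference(fps, rows)
    si <- vapply(rows, function(i) similarityIndex(X[i, ], ref, method),
                 numeric(1))
    names(si) <- sampleIds(fps)[rows]
    new("SimilarityReport", groupLabel = b, reference = ref, si = si,
        summary = list(mean = mean(si),
                       sd = if (length(si) >= 2) sd(si) else NA_real_,
                       min = min(si), max = max(si)))
  })
  names(out) <- unique(batches)
  out
}

#' Between-batch similarity of reference fingerprints
#'
#' Similarity index between every pair of batch median references — the
#' batch-level homogeneity summary.
#'
#' @param fps a [FingerprintSet-class].
#' @param method passed to [similarityIndex()].
#' @return Symmetric matrix of SI values (%), 100 on the diagonal.
#' @export
betweenBatchSimilarity <- function(fps, method = "cosine") {
  batches <- unique(batchIds(fps))
  refs <- lapply(batches, function(b)
    medianReference(fps, which(batchIds(fps) == b)))
  m <- matrix(100, length(batches), length(batches),
              dimnames = list(batches, batches))
  for (i in seq_along(batches))
    for (j in seq_along(batches))
      if (i != j) m[i, j] <- similarityIndex(refs[[i]], refs[[j]], method)
  m
}

#' PCA scores of a fingerprint panel
#'
#' Column-mean-centers the samples x points matrix and projects it on the
#' top-k right singular directions — the homogeneity diagnostic used to
#' inspect batch structure before modelling.
#'
#' @param fps a [FingerprintSet-class].
#' @param k number of components, at most `min(n_samples - 1, n_points)`.
#' @return list with `scores` (samples x k, zero column means) and
#'   `explained` (length-k non-increasing variance fractions in \[0, 1\]).
#' @export
pcaScores <- function(fps, k = 2) {
  X <- fingerprintMatrix(fps)
  n <- nrow(X); p <- ncol(X)
  if (k < 1 || k > min(n - 1, p))
    stop("k must lie in 1..min(n_samples - 1, n_points)")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(X)
  list(scores = scores, explained = (sv$d[seq_len(k)]^2) / sum(sv$d^2))
}
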