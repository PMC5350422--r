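#' @useDynLib qparfp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Core NIPALS for a single response. Returns weights/loadings for all
# components 1..A so coefficient vectors for any truncation can be formed
# cheaply (used by the LOO loop). For univariate y the NIPALS weight vector
# is exactly the normalized deflated covariance X_d' y_d — no inner
# iteration is needed.
nipals_core <- function(X, y, A, tolCov = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  xMean <- colMeans(X)
  yMean <- mean(y)
  Xd <- sweep(X, 2, xMean)
  yd <- y - yMean
  scale0 <- sqrt(sum(yd^2)) * max(1, sqrt(sum(Xd^2)))
  W <- matrix(0, p, A); P <- matrix(0, p, A); q <- numeric(A)
  a <- 0L
  while (a < A) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw <= tolCov * max(1, scale0)) break
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt <= .Machine$double.eps * max(1, scale0)) break
    pvec <- drop(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pvec)
    yd <- yd - t * qa
    a <- a + 1L
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa
  }
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       q = q[seq_len(a)], xMean = xMean, yMean = yMean, nComp = a)
}

# Regression vector for the first `a` components: B = W_a (P_a' W_a)^{-1} q_a
nipals_coef <- function(fit, a) {
  Wa <- fit$W[, seq_len(a), drop = FALSE]
  Pa <- fit$P[, seq_len(a), drop = FALSE]
  qa <- fit$q[seq_len(a)]
  drop(Wa %*% solve(crossprod(Pa, Wa), qa))
}

#' Fit a PLS regression model by NIPALS
#'
#' Univariate-response partial least squares on mean-centered data (no
#' variable scaling by default: all fingerprint variables share one
#' absorbance unit, and downstream region-perturbation logic needs
#' coefficients on the raw intensity scale). `autoscale = TRUE` opts into
#' unit-variance scaling of the columns.
#'
#' @param X training matrix (samples x variables).
#' @param y response vector.
#' @param nComponents number of latent components,
#'   `1..min(n_samples - 1, n_variables)`.
#' @param variableSubset indices of `X`'s columns within the full fingerprint
#'   grid (defaults to `1:ncol(X)`); recorded so the model knows its domain.
#' @param grid optional retention-time grid of the full fingerprint.
#' @param autoscale opt-in unit-variance scaling (default `FALSE`).
#' @return A [PLSModel-class].
#' @export
fitPLS <- function(X, y, nComponents, variableSubset = NULL, grid = numeric(),
                   autoscale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (any(!is.finite(X))) stop("X must be finite")
  if (var(y) == 0) stop("degenerate input: y has zero variance")
  if (nComponents < 1 || nComponents > min(n - 1, p))
    stop("nComponents must lie in 1..min(n_samples - 1, n_variables)")
  if (is.null(variableSubset)) variableSubset <- seq_len(p)
  if (length(variableSubset) != p)
    stop("variableSubset must name one grid index per column of X")
  X0 <- X
  sdv <- NULL
  if (autoscale) {
    sdv <- apply(X, 2, sd)
    sdv[sdv == 0] <- 1
    X <- sweep(X, 2, sdv, "/")
  }
  fit <- nipals_core(X, y, nComponents)
  if (fit$nComp < nComponents)
    warning("covariance exhausted after ", fit$nComp,
            " components; model truncated")
  b <- nipals_coef(fit, fit$nComp)
  if (autoscale) {
    b <- b / sdv
    fit$xMean <- fit$xMean * sdv
  }
  intercept <- fit$yMean - sum(fit$xMean * b)
  m <- new("PLSModel", nComponents = fit$nComp, xMean = fit$xMean,
           yMean = fit$yMean, weights = fit$W, xLoadings = fit$P,
           yLoadings = fit$q, coef = b, intercept = intercept,
           variableSubset = as.integer(variableSubset),
           fitted = numeric(), grid = as.numeric(grid))
  m@fitted <- predict(m, X0, restrict = FALSE)
  m
}

#' Predict activities from fingerprints
#'
#' Affine prediction `yhat = intercept + X[, variableSubset] %*% coef`.
#' By default `X` is a full-grid matrix and the model extracts its own
#' variable subset; pass `restrict = FALSE` when `X` already holds exactly
#' the model's variables.
#'
#' @param object a [PLSModel-class].
#' @param X matrix (or vector, treated as one sample) of fingerprints.
#' @param restrict extract `variableSubset` columns from `X` (default: only
#'   when `ncol(X)` differs from the model's variable count).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
setMethod("predict", "PLSModel", function(object, X, restrict = NULL, ...) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  p <- length(object@coef)
  if (is.null(restrict)) restrict <- ncol(X) != p
  if (restrict) {
    if (max(object@variableSubset) > ncol(X))
      stop("X has too few columns for this model's variable subset")
    X <- X[, object@variableSubset, drop = FALSE]
  }
  if (ncol(X) != p) stop("X column count does not match the model")
  drop(object@intercept + X %*% object@coef)
})

#' Leave-one-out component selection for PLS
#'
#' For each component count `a` in `1..maxComponents`, computes
#' `RMSECV_a = sqrt(mean((yhat_(-i) - y_i)^2))` over leave-one-out refits,
#' and returns the curve with its minimizer (ties go to the smaller, more
#' parsimonious count). Each held-out refit is performed once at
#' `maxComponents` and truncated, which is exact for NIPALS since components
#' are nested.
#'
#' @param X training matrix.
#' @param y response.
#' @param maxComponents largest count to assess, at most `n_samples - 2`.
#' @return list with `rmsecv` (named numeric, one value per component
#'   count) and `optimum` (integer).
#' @export
looCV <- function(X, y, maxComponents) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out selection needs at least 3 samples")
  maxComponents <- min(maxComponents, n - 2, ncol(X))
  if (maxComponents < 1) stop("maxComponents must be >= 1")
  errs <- matrix(NA_real_, n, maxComponents)
  for (i in seq_len(n)) {
    fit <- nipals_core(X[-i, , drop = FALSE], y[-i], maxComponents)
    for (a in seq_len(maxComponents)) {
      aa <- min(a, fit$nComp)
      if (aa < 1) next
      b <- nipals_coef(fit, aa)
      pred <- fit$yMean + sum((X[i, ] - fit$xMean) * b)
      errs[i, a] <- pred - y[i]
    }
  }
  rmsecv <- sqrt(colMeans(errs^2))
  names(rmsecv) <- seq_len(maxComponents)
  list(rmsecv = rmsecv, optimum = as.integer(which.min(rmsecv)))
}

#' Fit a PLS model with LOO-selected component count
#'
#' Convenience wrapper: run [looCV()], fit at the optimum, and return both.
#'
#' @inheritParams fitPLS
#' @param maxComponents cap on the component search (default
#'   `min(15, n - 2)`).
#' @return list with `model` ([PLSModel-class]), `rmsecv` (curve), and
#'   `optimum`.
#' @export
fitPLSCV <- function(X, y, maxComponents = NULL, variableSubset = NULL,
                     grid = numeric()) {
  X <- as.matrix(X)
  if (is.null(maxComponents)) maxComponents <- min(15L, nrow(X) - 2L)
  cv <- looCV(X, y, maxComponents)
  model <- fitPLS(X, y, cv$optimum, variableSubset = variableSubset,
                  grid = grid)
  list(model = model, rmsecv = cv$rmsecv, optimum = cv$optimum)
}

#' Serialize a PLS model to JSON
#'
#' @param model a [PLSModel-class].
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeModelJSON <- function(model, file) {
  jsonlite::write_json(list(
    n_components = model@nComponents, x_mean = model@xMean,
    y_mean = model@yMean, coef = model@coef, intercept = model@intercept,
    variable_subset = model@variableSubset,
    grid_hash = if (length(model@grid))
      sum(model@grid * seq_along(model@grid)) else NULL,
    scaling = "mean-centering only"),
    file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
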