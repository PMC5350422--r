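#' Elastic-net variable selection
#'
#' Fits the naive elastic net
#' `minimize ||y - X b||^2 + lambda1 * ||b||_1 + lambda2 * ||b||^2`
#' by cyclic coordinate descent on internally mean-centered data (fixed
#' ascending coordinate order, deterministic). The L1 penalty produces a
#' sparse support; the L2 penalty gives the grouping effect — coefficients
#' of highly correlated variables are drawn together, so whole peak regions
#' enter or leave the support jointly. Only the support is consumed by the
#' downstream EN-PLS refit, so no `(1 + lambda2)` rescaling of the
#' coefficients is applied (selection is invariant to it).
#'
#' Non-convergence at `maxIter` sweeps is reported via a warning and the
#' `converged` slot, not an error.
#'
#' @param X samples x variables matrix.
#' @param y response vector.
#' @param lambda1 L1 penalty weight (>= 0).
#' @param lambda2 L2 penalty weight (>= 0).
#' @param tol convergence tolerance on the maximum coordinate change per
#'   sweep (default 1e-6).
#' @param maxIter maximum number of sweeps (default 1e4).
#' @param betaInit optional warm-start coefficient vector.
#' @return An [ENSelection-class].
#' @export
fitElasticNet <- function(X, y, lambda1, lambda2, tol = 1e-6, maxIter = 1e4,
                          betaInit = NULL) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (lambda1 < 0 || lambda2 < 0) stop("penalties must be >= 0")
  if (is.null(betaInit)) betaInit <- numeric(ncol(X))
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  res <- en_coord_descent(Xc, yc, lambda1, lambda2, tol,
                          as.integer(maxIter), betaInit)
  if (!res$converged)
    warning("elastic net did not reach tolerance after ", res$iterations,
            " sweeps (max change ", signif(res$max_change, 3), ")")
  beta <- as.numeric(res$beta)
  new("ENSelection", lambda1 = lambda1, lambda2 = lambda2, beta = beta,
      support = which(beta != 0), nSelected = sum(beta != 0),
      iterations = as.integer(res$iterations),
      converged = isTRUE(res$converged),
      maxChange = as.numeric(res$max_change))
}

#' Smallest L1 penalty that zeroes every coefficient
#'
#' By the KKT conditions of the elastic net, `beta = 0` is optimal exactly
#' when `lambda1 >= 2 * max_j |x_j' (y - mean(y))|` on centered data.
#'
#' @param X samples x variables matrix.
#' @param y response.
#' @return The null threshold for `lambda1`.
#' @export
lambda1Max <- function(X, y) {
  Xc <- sweep(as.matrix(X), 2, colMeans(X))
  yc <- y - mean(y)
  2 * max(abs(drop(crossprod(Xc, yc))))
}

#' Default penalty grids for elastic-net tuning
#'
#' `lambda1`: 20 geometric points from the null threshold [lambda1Max()]
#' down to `1e-3` of it; `lambda2`: `{0.01, 0.1, 1, 10}`.
#'
#' @param X,y training data.
#' @param nLambda1 number of L1 grid points (default 20).
#' @return list with `lambda1` and `lambda2` grids.
#' @export
defaultENGrids <- function(X, y, nLambda1 = 20) {
  l1max <- lambda1Max(X, y)
  list(lambda1 = exp(seq(log(l1max), log(1e-3 * l1max),
                         length.out = nLambda1)),
       lambda2 = c(0.01, 0.1, 1, 10))
}

en_fold_assignment <- function(n, folds) {
  # contiguous blocks in the given (Kennard-Stone) row order, deterministic
  rep(seq_len(folds), each = ceiling(n / folds))[seq_len(n)]
}

#' Cross-validated elastic-net penalty tuning
#'
#' Grid search over `(lambda1, lambda2)` scored by k-fold cross-validated
#' RMSE of the downstream EN-PLS fit: per fold, the elastic net is fitted on
#' the in-fold data, a PLS model is refit on the selected support (component
#' count by leave-one-out within the fold training data), and the held-out
#' block is predicted. Folds are contiguous blocks of the row order as given
#' (the Kennard-Stone selection order), so tuning is deterministic. Ties in
#' CV RMSE go to the larger `lambda1` (the sparser model); a grid point whose
#' selection is empty in any fold scores `Inf`.
#'
#' @param X training matrix (rows in Kennard-Stone order).
#' @param y training response.
#' @param lambda1Grid,lambda2Grid penalty grids (default [defaultENGrids()]).
#' @param folds number of folds (2..n), default 5.
#' @param maxComponents cap for the per-fold PLS component search.
#' @param tol,maxIter passed to [fitElasticNet()].
#' @return list with `lambda1`, `lambda2` (the winners) and `cv` (data.frame
#'   of the full grid with CV RMSE).
#' @export
tuneEN <- function(X, y, lambda1Grid = NULL, lambda2Grid = NULL, folds = 5,
                   maxComponents = NULL, tol = 1e-6, maxIter = 1e4) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (folds < 2 || folds > n) stop("folds must lie in 2..n_train")
  if (is.null(lambda1Grid) || is.null(lambda2Grid)) {
    g <- defaultENGrids(X, y)
    if (is.null(lambda1Grid)) lambda1Grid <- g$lambda1
    if (is.null(lambda2Grid)) lambda2Grid <- g$lambda2
  }
  if (any(lambda1Grid < 0) || any(lambda2Grid < 0))
    stop("penalty grids must be >= 0")
  if (is.null(maxComponents)) maxComponents <- min(10L, n - 3L)
  fold <- en_fold_assignment(n, folds)
  # descending lambda1 within each lambda2 so each fit warm-starts from the
  # previous (sparser) solution
  lambda1Grid <- sort(lambda1Grid, decreasing = TRUE)
  grid <- expand.grid(lambda1 = lambda1Grid, lambda2 = lambda2Grid)
  sqerr <- matrix(0, nrow(grid), 1)
  nPred <- numeric(nrow(grid))
  bad <- logical(nrow(grid))
  for (f in seq_len(folds)) {
    idx <- fold != f
    Xf <- X[idx, , drop = FALSE]; yf <- y[idx]
    for (l2 in lambda2Grid) {
      warm <- numeric(ncol(X))
      for (l1 in lambda1Grid) {
        g <- which(grid$lambda1 == l1 & grid$lambda2 == l2)
        en <- suppressWarnings(
          fitElasticNet(Xf, yf, l1, l2, tol, maxIter, betaInit = warm))
        warm <- en@beta
        if (en@nSelected == 0) { bad[g] <- TRUE; next }
        Xs <- Xf[, en@support, drop = FALSE]
        cap <- max(1L, min(maxComponents, en@nSelected, sum(idx) - 2L))
        cv <- looCV(Xs, yf, cap)
        pm <- fitPLS(Xs, yf, cv$optimum)
        pred <- predict(pm, X[!idx, en@support, drop = FALSE],
                        restrict = FALSE)
        sqerr[g] <- sqerr[g] + sum((pred - y[!idx])^2)
        nPred[g] <- nPred[g] + sum(!idx)
      }
    }
  }
  grid$rmse <- ifelse(bad, Inf, sqrt(sqerr / pmax(nPred, 1)))
  # minimal CV RMSE; ties -> larger lambda1 (sparser)
  ord <- order(grid$rmse, -grid$lambda1)
  best <- grid[ord[1], ]
  list(lambda1 = best$lambda1, lambda2 = best$lambda2, cv = grid)
}

#' Elastic-net-selected PLS (EN-PLS)
#'
#' Fits the elastic net on the training data, restricts the matrix to the
#' selected support, and refits a PLS model there with leave-one-out
#' component selection. The returned PLS model's `variableSubset` is the
#' elastic-net support, so it predicts directly from full-grid fingerprints.
#'
#' @param X full-grid training matrix.
#' @param y training response.
#' @param lambda1,lambda2 elastic-net penalties.
#' @param maxComponents cap for the component search (default
#'   `min(15, n - 2)`).
#' @param grid optional retention-time grid, stored in the model.
#' @param tol,maxIter passed to [fitElasticNet()].
#' @return list with `selection` ([ENSelection-class]), `model`
#'   ([PLSModel-class]), and `rmsecv` (the LOO curve on the support).
#' @export
fitENPLS <- function(X, y, lambda1, lambda2, maxComponents = NULL,
                     grid = numeric(), tol = 1e-6, maxIter = 1e4) {
  X <- as.matrix(X)
  en <- fitElasticNet(X, y, lambda1, lambda2, tol, maxIter)
  if (en@nSelected == 0)
    stop("degenerate selection: elastic net selected no variables; ",
         "decrease lambda1")
  Xs <- X[, en@support, drop = FALSE]
  if (is.null(maxComponents)) maxComponents <- min(15L, nrow(X) - 2L)
  cap <- min(maxComponents, en@nSelected)
  cv <- looCV(Xs, y, cap)
  model <- fitPLS(Xs, y, cv$optimum, variableSubset = en@support, grid = grid)
  list(selection = en, model = model, rmsecv = cv$rmsecv)
}

#' Serialize an elastic-net selection to JSON
#'
#' Sparse triplet form: support indices and their coefficients.
#'
#' @param en an [ENSelection-class].
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeSelectionJSON <- function(en, file) {
  jsonlite::write_json(list(
    lambda1 = en@lambda1, lambda2 = en@lambda2,
    support = en@support, beta = en@beta[en@support],
    n_variables = length(en@beta), n_selected = en@nSelected,
    iterations = en@iterations, converged = en@converged,
    max_change = en@maxChange),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
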