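test_that("unpenalized elastic net equals least squares on tall full-rank X", {
  set.seed(2)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- rnorm(40)
  en <- fitElasticNet(X, y, 0, 0)
  ls <- lm.fit(cbind(1, sweep(X, 2, colMeans(X))), y)
  expect_equal(en@beta, unname(ls$coefficients[-1]), tolerance = 1e-6)
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  Q <- qr.Q(qr(matrix(rnorm(30 * 6), 30, 6)))
  Q <- qr.Q(qr(sweep(Q, 2, colMeans(Q))))   # orthonormal, mean-zero columns
  set.seed(14)
  y <- rnorm(30, sd = 2)
  bOls <- drop(crossprod(Q, y - mean(y)))
  for (l1 in c(0.5, 1.5)) for (l2 in c(0, 0.3, 2)) {
    en <- fitElasticNet(Q, y, l1, l2, tol = 1e-10)
    soft <- sign(bOls) * pmax(abs(bOls) - l1 / 2, 0) / (1 + l2)
    expect_equal(en@beta, soft, tolerance = 1e-8)
  }
})

test_that("the KKT null condition empties the support", {
  set.seed(15)
  X <- matrix(rnorm(25 * 40), 25, 40)
  y <- rnorm(25)
  l1max <- lambda1Max(X, y)
  en <- fitElasticNet(X, y, l1max * 1.0000001, 1)
  expect_equal(en@nSelected, 0L)
  enBelow <- fitElasticNet(X, y, l1max * 0.9, 1)
  expect_gt(enBelow@nSelected, 0L)
})

test_that("stationarity holds at convergence for every coordinate", {
  set.seed(16)
  X <- matrix(rnorm(30 * 50), 30, 50)
  y <- drop(X[, 1] - 2 * X[, 2]) + rnorm(30, sd = 0.5)
  tol <- 1e-8
  l1 <- 4; l2 <- 1.5
  en <- fitElasticNet(X, y, l1, l2, tol = tol)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  r <- yc - Xc %*% en@beta
  grad <- -2 * drop(crossprod(Xc, r)) + 2 * l2 * en@beta
  xx <- colSums(Xc^2)
  for (j in seq_len(50)) {
    if (en@beta[j] != 0) {
      expect_lt(abs(grad[j] + l1 * sign(en@beta[j])), 10 * tol * (xx[j] + l2))
    } else {
      expect_lte(abs(grad[j]), l1 + 10 * tol * (xx[j] + l2))
    }
  }
})

test_that("the penalized objective is non-increasing across sweeps", {
  set.seed(17)
  X <- matrix(rnorm(20 * 30), 20, 30)
  y <- rnorm(20)
  l1 <- 2; l2 <- 0.5
  objs <- vapply(c(1, 2, 3, 5, 8, 15, 40), function(k) {
    en <- suppressWarnings(fitElasticNet(X, y, l1, l2, tol = 0, maxIter = k))
    en_objective(X, y, en@beta, l1, l2)
  }, 0)
  expect_true(all(diff(objs) <= 1e-8 * objs[1]))
})

test_that("the ridge penalty equalizes duplicated informative columns", {
  set.seed(18)
  x <- rnorm(40)
  X <- cbind(x, x, matrix(rnorm(40 * 8), 40, 8))
  y <- 3 * x + rnorm(40, sd = 0.3)
  en <- fitElasticNet(X, y, 1, 1, tol = 1e-10)
  expect_gt(abs(en@beta[1]), 0)
  expect_lt(abs(en@beta[1] - en@beta[2]), 1e-6)
})

test_that("coefficients match independent solvers on the same objective", {
  skip_if_not_installed("glmnet")
  set.seed(19)
  n <- 30
  X <- matrix(rnorm(n * 12), n, 12)
  y <- drop(X[, 1] * 2 - X[, 3]) + rnorm(n, sd = 0.4)
  # lasso limit: our ||y-Xb||^2 + l1|b| equals 2n * glmnet's
  # (1/2n)RSS + lambda|b| at lambda = l1/(2n)
  for (l1 in c(1, 3, 8)) {
    g <- glmnet::glmnet(X, y, alpha = 1, lambda = l1 / (2 * n),
                        standardize = FALSE, thresh = 1e-16, maxit = 1e7)
    en <- fitElasticNet(X, y, l1, 0, tol = 1e-12)
    expect_equal(en@beta, as.numeric(g$beta), tolerance = 1e-6)
  }
  # ridge limit: analytic solution (X'X + l2 I)^-1 X'y on centered data
  l2 <- 2
  en <- fitElasticNet(X, y, 0, l2, tol = 1e-12)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  analytic <- drop(solve(crossprod(Xc) + l2 * diag(12), crossprod(Xc, yc)))
  expect_equal(en@beta, analytic, tolerance = 1e-10)
})

test_that("tuning honours single-point grids and rejects bad ones", {
  set.seed(20)
  X <- matrix(rnorm(20 * 15), 20, 15)
  y <- drop(X[, 1:3] %*% c(2, -1, 1)) + rnorm(20, sd = 0.3)
  tn <- tuneEN(X, y, lambda1Grid = 1.5, lambda2Grid = 0.5, folds = 4)
  expect_equal(tn$lambda1, 1.5)
  expect_equal(tn$lambda2, 0.5)
  expect_error(tuneEN(X, y, lambda1Grid = c(-1, 1), lambda2Grid = 1),
               ">= 0")
  expect_error(tuneEN(X, y, folds = 1), "folds")
})

test_that("tuning induces sparsity on sparse-truth data for most seeds", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30; p <- 120
    X <- matrix(rnorm(n * p), n, p)
    beta <- numeric(p); beta[sample(p, 10)] <- runif(10, 1, 2) * sample(c(-1, 1), 10, TRUE)
    y <- drop(X %*% beta) + rnorm(n, sd = 1)
    g <- defaultENGrids(X, y, nLambda1 = 8)
    tn <- tuneEN(X, y, lambda1Grid = g$lambda1, lambda2Grid = c(0.1, 1),
                 folds = 3, maxComponents = 6)
    if (tn$lambda1 > 0) hits <- hits + 1
  }
  expect_gte(hits, 16)  # sparsity chosen on at least 80% of seeds
})

test_that("EN-PLS reduces to plain PLS when nothing is deselected", {
  set.seed(21)
  X <- matrix(rnorm(25 * 6), 25, 6)
  y <- drop(X %*% c(1, -1, 2, 0, 0.5, -2)) + rnorm(25, sd = 0.2)
  ef <- fitENPLS(X, y, 0, 0, maxComponents = 5)
  expect_equal(sort(ef$selection@support), 1:6)
  direct <- fitPLSCV(X, y, maxComponents = 5)
  expect_equal(ef$model@coef, direct$model@coef, tolerance = 1e-8)
})

test_that("a single-variable support caps the downstream model at 1 component", {
  set.seed(22)
  x <- rnorm(30)
  X <- cbind(x, matrix(rnorm(30 * 10, sd = 0.05), 30, 10))
  y <- 4 * x + rnorm(30, sd = 0.2)
  l1m <- lambda1Max(X, y)
  ef <- fitENPLS(X, y, 0.8 * l1m, 0)
  expect_equal(ef$selection@nSelected, 1L)
  expect_equal(ef$model@nComponents, 1L)
})

test_that("an empty selection raises a degenerate-selection error", {
  set.seed(23)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- rnorm(20)
  expect_error(fitENPLS(X, y, 10 * lambda1Max(X, y), 1),
               "decrease lambda1")
})
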