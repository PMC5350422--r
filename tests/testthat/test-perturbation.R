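# a model with a hand-set coefficient vector, for exact-arithmetic checks
stub_model <- function(coef, grid = seq_along(coef)) {
  new("PLSModel", nComponents = 1L, xMean = numeric(length(coef)),
      yMean = 0, weights = matrix(0, length(coef), 1),
      xLoadings = matrix(0, length(coef), 1), yLoadings = 0,
      coef = coef, intercept = 0,
      variableSubset = seq_along(coef), fitted = numeric(),
      grid = as.numeric(grid))
}

test_that("mean fingerprint is the column mean", {
  X <- rbind(c(0, 0, 1), c(2, 2, 3))
  expect_equal(meanFingerprint(X), c(1, 1, 2))
  fps <- FingerprintSet(X, 1:3)
  expect_equal(meanFingerprint(fps), c(1, 1, 2))
  p <- small_panel(seed = 2)
  expect_length(meanFingerprint(raw_matrix(p)), 201)
})

test_that("region selection partitions a hand-checked coefficient vector", {
  m <- stub_model(c(1, 1, 0, 0, -2, -2))
  regions <- selectRegions(m, nPos = 1, nNeg = 1, nZero = 1, minWidth = 2)
  expect_equal(nrow(regions), 3)
  pos <- regions[regions$category == "positive", ]
  neg <- regions[regions$category == "negative", ]
  zero <- regions[regions$category == "zero", ]
  expect_equal(c(pos$start, pos$end), c(1, 2))
  expect_equal(c(neg$start, neg$end), c(5, 6))
  expect_equal(c(zero$start, zero$end), c(3, 4))
  expect_equal(pos$aggregate_coefficient, 2)
  expect_equal(neg$aggregate_coefficient, -4)
  expect_equal(zero$aggregate_coefficient, 0)
})

test_that("region selection errors when a category cannot be filled", {
  expect_error(selectRegions(stub_model(rep(0, 10)), nPos = 1),
               "all coefficients are zero")
  m <- stub_model(c(1, 1, 1, 1, 1, 1))
  expect_error(selectRegions(m, nPos = 1, nNeg = 1, nZero = 0, minWidth = 2),
               "negative")
})

test_that("a fitted synthetic model yields 13 disjoint regions on request", {
  # noise-free signal so that off-peak grid regions carry (numerically) zero
  # coefficients and a zero category exists for plain PLS
  p <- study_panel(seed = 5, baselineAmplitude = 0, rtJitterSd = 0,
                   noiseSd = 0)
  X <- raw_matrix(p); y <- p$activities
  grid <- p$chromatograms[[1]]@rt
  ks <- kennardStone(X, 48)
  m <- fitPLSCV(X[trainIndices(ks), ], y[trainIndices(ks)],
                grid = grid)$model
  regions <- selectRegions(m, nPos = 6, nNeg = 5, nZero = 2, minWidth = 5)
  expect_equal(nrow(regions), 13)
  expect_equal(sum(regions$category == "positive"), 6)
  expect_equal(sum(regions$category == "negative"), 5)
  expect_equal(sum(regions$category == "zero"), 2)
  ord <- regions[order(regions$start), ]
  expect_true(all(ord$start[-1] > ord$end[-nrow(ord)]))  # pairwise disjoint
})

test_that("perturbation deltas follow the model's linearity exactly", {
  set.seed(31)
  coef <- c(0.5, 0.5, 0, 0, -1, -1, 0.2, 0.2)
  m <- stub_model(coef)
  base <- runif(8, 1, 5)
  regions <- data.frame(start = c(1, 5, 3), end = c(2, 6, 4))
  for (r in 1:3) for (s in c(0.5, 1, 2)) {
    got <- perturbAndPredict(m, base, regions[r, ], s)
    want <- s * sum(coef[regions$start[r]:regions$end[r]] *
                    base[regions$start[r]:regions$end[r]])
    expect_equal(got, want, tolerance = 1e-12)
  }
  # zero-coefficient region: exactly zero at every scale
  for (s in c(0.5, 1, 2))
    expect_identical(perturbAndPredict(m, base, regions[3, ], s), 0)
  # zero fractional increase
  expect_equal(perturbAndPredict(m, base, regions[1, ], 0), 0)
  # 200% delta = 4 x 50% delta = 2 x 100% delta
  d50 <- perturbAndPredict(m, base, regions[1, ], 0.5)
  d100 <- perturbAndPredict(m, base, regions[1, ], 1)
  d200 <- perturbAndPredict(m, base, regions[1, ], 2)
  expect_equal(d200, 4 * d50, tolerance = 1e-12)
  expect_equal(d200, 2 * d100, tolerance = 1e-12)
  expect_error(perturbAndPredict(m, base, data.frame(start = 7, end = 12), 1),
               "outside")
})

test_that("disjoint-region perturbations are additive", {
  set.seed(32)
  p <- small_panel(seed = 7)
  fps <- preprocessPanel(p$chromatograms, activities = p$activities)
  X <- fingerprintMatrix(fps); y <- activities(fps)
  m <- fitPLS(X, y, 4, grid = rtGrid(fps))
  base <- meanFingerprint(fps)
  r1 <- data.frame(start = 20, end = 35)
  r2 <- data.frame(start = 90, end = 110)
  d1 <- perturbAndPredict(m, base, r1, 1)
  d2 <- perturbAndPredict(m, base, r2, 1)
  both <- base
  both[20:35] <- both[20:35] * 2
  both[90:110] <- both[90:110] * 2
  dBoth <- unname(predict(m, both) - predict(m, base))
  expect_equal(dBoth, d1 + d2, tolerance = 1e-9 * max(1, abs(dBoth)))
  # sign concordance on a positive base
  basePos <- abs(base) + 0.1
  beta <- coefVector(m, full = TRUE)
  for (r in list(r1, r2)) {
    agg <- sum(beta[r$start:r$end] * basePos[r$start:r$end])
    expect_equal(sign(perturbAndPredict(m, basePos, r, 1)), sign(agg))
  }
})

test_that("the perturbation table covers every region, model and scale", {
  mPls <- stub_model(c(1, 1, 0, 0, -2, -2))
  mEn <- stub_model(c(2, 0, 0, 0, -1, 0))
  regions <- selectRegions(mPls, nPos = 1, nNeg = 1, nZero = 1, minWidth = 2)
  base <- c(1, 2, 3, 4, 5, 6)
  tab <- perturbationTable(list(PLS = mPls, ENPLS = mEn), base, regions)
  expect_equal(nrow(tab), 6)  # 3 regions x 2 models
  expect_setequal(unique(tab$model), c("PLS", "ENPLS"))
  expect_true(all(c("delta_50", "delta_100", "delta_200") %in% colnames(tab)))
  # zero-coefficient region rows are all zero
  zrow <- tab[tab$category == "zero" & tab$model == "PLS", ]
  expect_equal(unlist(zrow[c("delta_50", "delta_100", "delta_200")]),
               c(delta_50 = 0, delta_100 = 0, delta_200 = 0))
  # dose-response: positive-region deltas strictly increase with the scale
  prow <- tab[tab$category == "positive" & tab$model == "PLS", ]
  expect_true(prow$delta_50 < prow$delta_100 & prow$delta_100 < prow$delta_200)
  # exact linear scaling in every row with nonzero coefficient
  nz <- tab[abs(tab$coefficient) > 0, ]
  expect_equal(nz$delta_200, 4 * nz$delta_50, tolerance = 1e-9)
  expect_equal(nz$delta_200, 2 * nz$delta_100, tolerance = 1e-9)
})
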