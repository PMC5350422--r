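fps_from_matrix <- function(X, batch = "b1") {
  FingerprintSet(X, seq_len(ncol(X)), batchIds = batch)
}

test_that("median reference matches pointwise medians", {
  X <- rbind(c(1, 1), c(2, 2), c(9, 9))
  fps <- fps_from_matrix(X)
  expect_equal(medianReference(fps, 1), c(1, 1))
  expect_equal(medianReference(fps), c(2, 2))
  expect_equal(medianReference(fps, c(1, 2)), c(1.5, 1.5))
  expect_error(medianReference(fps, integer()), "empty")
})

test_that("similarity index is the percent cosine with its edge cases", {
  expect_equal(similarityIndex(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(similarityIndex(c(1, 0), c(0, 1)), 0)
  expect_equal(similarityIndex(c(1, 0), c(1, 1)), 100 / sqrt(2),
               tolerance = 1e-10)
  expect_equal(round(similarityIndex(c(1, 0), c(1, 1)), 2), 70.71)
  expect_equal(similarityIndex(c(0, 0), c(1, 1)), 0)
  expect_error(similarityIndex(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(similarityIndex(c(1, 2), c(0, 0)), "all zero")
})

test_that("similarity index is scale-invariant and permutation-consistent", {
  set.seed(42)
  for (i in 1:20) {
    x <- abs(rnorm(50)); ref <- abs(rnorm(50))
    c <- runif(1, 0.1, 10)
    expect_equal(similarityIndex(c * x, ref), similarityIndex(x, ref),
                 tolerance = 1e-10)
    perm <- sample(50)
    expect_equal(similarityIndex(x[perm], ref[perm]), similarityIndex(x, ref),
                 tolerance = 1e-10)
  }
})

test_that("group similarity reports per-batch references and summaries", {
  X <- rbind(c(1, 2, 3), c(1, 2, 3), c(3, 1, 0), c(3, 1.2, 0.1))
  fps <- fps_from_matrix(X, batch = c("A", "A", "B", "B"))
  reps <- groupSimilarity(fps)
  expect_named(reps, c("A", "B"))
  expect_equal(unname(similarityIndices(reps$A)), c(100, 100))
  expect_equal(reps$A@summary$mean, 100)
  expect_equal(reps$A@summary$sd, 0)
  # permuting the rows leaves summaries unchanged
  perm <- c(3, 1, 4, 2)
  reps2 <- groupSimilarity(fps_from_matrix(X[perm, ],
                                           batch = c("B", "A", "B", "A")))
  expect_equal(reps2$A@summary, reps$A@summary)
  expect_equal(reps2$B@summary, reps$B@summary)
})

test_that("single-member batches report an undefined sd", {
  X <- rbind(c(1, 2), c(2, 1), c(1, 2))
  reps <- groupSimilarity(fps_from_matrix(X, batch = c("A", "A", "B")))
  expect_true(is.na(reps$B@summary$sd))
  expect_equal(unname(similarityIndices(reps$B)), 100)
})

test_that("the default study-scale panel keeps within-batch similarity high", {
  p <- study_panel(seed = 2)
  fps <- preprocessPanel(p$chromatograms, activities = p$activities)
  reps <- groupSimilarity(fps)
  allSI <- unlist(lapply(reps, similarityIndices))
  expect_length(allSI, 72)
  expect_true(all(allSI >= 85))
  bb <- betweenBatchSimilarity(fps)
  expect_true(all(diag(bb) == 100))
  expect_true(all(bb >= 80))
})

test_that("PCA scores diagnose rank, centering and batch structure", {
  # rank-1 panel
  profile <- c(1, 3, 2, 5, 4)
  X <- outer(c(1, 2, 3, 4), profile)
  sc <- pcaScores(fps_from_matrix(X), 2)
  expect_gte(sc$explained[1], 0.999)
  expect_equal(colMeans(sc$scores), c(0, 0), tolerance = 1e-10)

  # variance conservation at full rank
  set.seed(7)
  X <- matrix(rnorm(8 * 6), 8, 6)
  sc <- pcaScores(fps_from_matrix(X), 6)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_equal(sum(sc$scores^2), sum(Xc^2), tolerance = 1e-8)
  expect_true(all(diff(sc$explained) <= 1e-12))
  expect_true(all(sc$explained >= 0 & sc$explained <= 1))

  expect_error(pcaScores(fps_from_matrix(X), 8), "k must lie")

  # strong batch effect separates batch centroids in score space
  p <- small_panel(seed = 10, batchEffectSd = 0.6)
  fps <- preprocessPanel(p$chromatograms)
  sc <- pcaScores(fps, 2)
  batch <- rep(1:3, each = 8)
  centroids <- t(vapply(1:3, function(b)
    colMeans(sc$scores[batch == b, , drop = FALSE]), numeric(2)))
  withinSd <- mean(vapply(1:3, function(b)
    mean(apply(sc$scores[batch == b, , drop = FALSE], 2, sd)), 0))
  expect_gt(min(dist(centroids)), withinSd)
})
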