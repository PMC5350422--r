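make_chrom <- function(intensity, rt = seq_along(intensity), id = "s1") {
  Chromatogram(rt = rt, intensity = intensity, sampleId = id, batchId = "b1")
}

test_that("baseline correction removes drift and leaves flat traces at zero", {
  flat <- make_chrom(numeric(200))
  out <- correctBaseline(flat)
  expect_lt(max(abs(out@intensity)), 1e-8)

  # known linear drift under three Gaussian peaks
  g <- seq(0, 50, by = 0.1)
  drift <- 2 + 0.3 * g             # amplitude 15 over the run
  peaks <- 100 * exp(-(g - 12)^2 / 0.5) + 80 * exp(-(g - 25)^2 / 0.8) +
    120 * exp(-(g - 38)^2 / 0.3)
  ch <- make_chrom(drift + peaks, rt = g)
  out <- correctBaseline(ch)
  offPeak <- abs(g - 12) > 3 & abs(g - 25) > 3 & abs(g - 38) > 3
  driftAmplitude <- max(drift) - min(drift)
  expect_lt(abs(median(out@intensity[offPeak])), 0.02 * driftAmplitude)

  # idempotence: a second pass changes little
  out2 <- correctBaseline(out)
  effect1 <- abs(median(ch@intensity[offPeak]) -
                 median(out@intensity[offPeak]))
  effect2 <- abs(median(out@intensity[offPeak]) -
                 median(out2@intensity[offPeak]))
  expect_lt(effect2, 0.1 * effect1)
})

test_that("baseline correction validates its inputs", {
  expect_error(correctBaseline(make_chrom(numeric(5))), "at least 10")
  expect_error(alsBaseline(numeric(100), asymmetry = 1.5), "asymmetry")
  expect_error(alsBaseline(numeric(100), smoothness = -1), "smoothness")
})

test_that("baseline correction is shift-equivariant away from the edges", {
  # free boundary conditions perturb the estimate near the trace ends, and
  # the iterated asymmetric reweighting switches discretely as points cross
  # the baseline, so equivariance is asserted on the interior at 1e-4 of
  # the trace norm (the edge regions themselves differ at the 1e-3 level)
  g <- seq_len(500)
  y <- 80 * exp(-(g - 150)^2 / 512) + 60 * exp(-(g - 250)^2 / 512) +
    90 * exp(-(g - 350)^2 / 512)
  shifted <- c(numeric(3), y[1:497])
  d <- (shifted - alsBaseline(shifted)) - c(numeric(3), (y - alsBaseline(y))[1:497])
  interior <- 100:400
  expect_lt(max(abs(d[interior])), 1e-4 * sqrt(sum(y^2)))
})

test_that("alignment recovers known shifts and respects its bounds", {
  g <- seq(0, 20, by = 0.1)
  ref <- 50 * exp(-(g - 8)^2 / 0.5) + 30 * exp(-(g - 14)^2 / 0.3)
  ch <- make_chrom(ref, rt = g)

  # identity
  out <- alignToReference(ch, ref, maxShift = 1)
  expect_identical(out@intensity, ref)

  # rolled right by 5 grid steps -> recovered
  rolled <- c(numeric(5), ref[1:(length(ref) - 5)])
  out <- alignToReference(make_chrom(rolled, rt = g), ref, maxShift = 1)
  expect_gt(cor(out@intensity, ref), 0.999)

  # best shift outside the window: clamped, never exceeds the bound
  rolled10 <- c(numeric(10), ref[1:(length(ref) - 10)])
  out <- alignToReference(make_chrom(rolled10, rt = g), ref, maxShift = 0.3)
  lag <- which.max(out@intensity) - which.max(ref)
  expect_lte(abs(lag), 10 - 3)  # moved by at most 3 steps of the 10 needed

  expect_error(alignToReference(ch, ref[-1], maxShift = 1), "same grid")
  expect_error(alignToReference(ch, ref, maxShift = 15), "half the grid span")
})

test_that("alignment preserves point count and zero-fills at most the window", {
  g <- seq(0, 20, by = 0.1)
  x <- 50 * exp(-(g - 10)^2 / 0.5) + 1
  ref <- c(numeric(4), x[1:(length(x) - 4)])
  out <- alignToReference(make_chrom(x, rt = g), ref, maxShift = 0.5)
  expect_length(out@intensity, length(x))
  expect_lte(sum(out@intensity == 0), 5)
})

test_that("buildMatrix interpolates exactly at shared nodes and checks coverage", {
  g <- seq(0, 10, by = 0.1)
  x <- sin(g) + 2
  ch <- make_chrom(x, rt = g)
  fps <- buildMatrix(list(ch), g)
  expect_equal(unname(fingerprintMatrix(fps)[1, ]), x)

  half <- g[seq(1, length(g), by = 2)]
  fps2 <- buildMatrix(list(ch), half)
  expect_equal(unname(fingerprintMatrix(fps2)[1, ]), x[seq(1, length(g), by = 2)])

  wide <- seq(-1, 11, by = 0.1)
  expect_error(buildMatrix(list(ch), wide), "s1")
})

test_that("a full synthetic panel preprocesses into a clean matrix", {
  fps <- small_fps(seed = 8)
  X <- fingerprintMatrix(fps)
  expect_equal(dim(X), c(24, 201))
  expect_true(all(is.finite(X)))
  steps <- vapply(preprocessingLog(fps), `[[`, "", "step")
  expect_true(all(c("baseline_als", "build_matrix", "align_to_median") %in% steps))
})

test_that("preprocessing is deterministic", {
  f1 <- small_fps(seed = 8)
  f2 <- small_fps(seed = 8)
  expect_identical(fingerprintMatrix(f1), fingerprintMatrix(f2))
})
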