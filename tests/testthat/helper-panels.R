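# Shared fixture builders. Panels are generated at test time; the "small"
# configuration (12 peaks, 0-20 min at 0.1 min -> 201 variables, 3 x 8
# samples) keeps single tests fast while preserving the full structure of
# the default study-scale design (40 peaks, 0-70 min at 0.05 min, 3 x 24).

small_library <- function(seed = 5) {
  generatePeakLibrary(12, c(0, 20), 0.1, seed = seed)
}

small_panel <- function(seed = 3, ...) {
  simulatePanel(small_library(), generationConfig(nPerBatch = 8, seed = seed, ...))
}

small_fps <- function(seed = 3, ...) {
  p <- small_panel(seed = seed, ...)
  preprocessPanel(p$chromatograms, activities = p$activities)
}

study_panel <- function(seed = 1, libSeed = 11, ...) {
  lib <- generatePeakLibrary(40, c(0, 70), 0.05, seed = libSeed)
  simulatePanel(lib, generationConfig(seed = seed, ...))
}

# raw (unpreprocessed) intensity matrix of a panel
raw_matrix <- function(panel) {
  t(vapply(panel$chromatograms, function(c) c@intensity,
           numeric(length(panel$chromatograms[[1]]@rt))))
}

# penalized elastic-net objective, used by property tests
en_objective <- function(X, y, beta, lambda1, lambda2) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  sum((yc - Xc %*% beta)^2) + lambda1 * sum(abs(beta)) + lambda2 * sum(beta^2)
}
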