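# shared fixtures, built in code at test time

# a small, quiet configuration for fast unit tests
quietConfig <- function(nCells = 12, ...) {
  simConfig(nCells = nCells, noiseSd = 0, bleachCoefs = c(0, 0), ...)
}

# one silent cell, no noise, no bleach: the trace is the constant baseline
silentConfig <- function(f0 = 100) {
  simConfig(nCells = 1, classProportions = c(0, 0, 0, 1), noiseSd = 0,
            bleachCoefs = c(0, 0), f0Baseline = f0)
}

# features through the default processing chain, with ground truth
simFeatures <- function(preset = "control", seed = 1, nCells = 160, ...) {
  sim <- simulatePopulation(conditionPreset(preset, nCells = nCells, ...),
                            seed = seed, condition = preset)
  nts <- normalizeTraces(simTraces(sim))
  list(features = computeFeatures(nts), truth = groundTruth(sim), nts = nts)
}

# disc footprint mask, for brute-force IoU oracles
discMask <- function(h, w, centers, radius) {
  L <- matrix(0L, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  for (i in seq_len(nrow(centers))) {
    L[(rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <= radius^2] <- i
  }
  L
}
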