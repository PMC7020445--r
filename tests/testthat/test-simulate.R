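test_that("a silent cell without noise or bleach is a constant baseline", {
  sim <- simulatePopulation(silentConfig(f0 = 100), seed = 1)
  expect_equal(unname(rawTraces(simTraces(sim))[1, ]),
               rep(100, 60), tolerance = 1e-12)
  expect_identical(groundTruth(sim)$true_spike_count, 0L)
})

test_that("simulation is bit-identical for a repeated (config, seed)", {
  cfg <- simConfig(nCells = 15)
  a <- simulatePopulation(cfg, seed = 42)
  b <- simulatePopulation(cfg, seed = 42)
  expect_identical(rawTraces(simTraces(a)), rawTraces(simTraces(b)))
  expect_identical(as.list(groundTruth(a)$spike_frames),
                   as.list(groundTruth(b)$spike_frames))
  c_ <- simulatePopulation(cfg, seed = 43)
  expect_false(identical(rawTraces(simTraces(a)), rawTraces(simTraces(c_))))
})

test_that("plain Poisson spike counts match the configured rate", {
  cfg <- simConfig(nCells = 1000,
                   classProportions = c(1, 0, 0, 0),
                   spikeRate = c(12, 0, 0, 0),
                   nFrames = 120,      # enough room for ~12 separated events
                   enforceCountRange = FALSE)
  sim <- simulatePopulation(cfg, seed = 7)
  k <- groundTruth(sim)$true_spike_count
  se <- sd(k) / sqrt(length(k))
  expect_lt(abs(mean(k) - 12), 3 * se)
})

test_that("class composition is exact and spike times respect constraints", {
  cfg <- simConfig(nCells = 160)
  sim <- simulatePopulation(cfg, seed = 5)
  gt <- groundTruth(sim)
  expect_equal(as.vector(table(factor(gt$true_class,
                                      levels = activityClasses()))),
               c(16, 48, 64, 32))
  for (f in as.list(gt$spike_frames)) {
    if (length(f) == 0) next
    expect_true(all(f >= 3 & f <= 59))          # inside the recording
    if (length(f) > 1) {
      expect_true(all(diff(f) >= 2))            # resolvable at 10 s sampling
    }
  }
  # enforced count ranges keep classes boundary-consistent
  counts <- gt$true_spike_count
  expect_true(all(counts[gt$true_class == "hyperactive"] >= 7))
  expect_true(all(counts[gt$true_class == "moderate"] %in% 1:6))
  expect_true(all(counts[gt$true_class == "low"] %in% 1:6))
  expect_true(all(counts[gt$true_class == "silent"] == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(classProportions = c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
  expect_error(simConfig(noiseSd = -1), "non-negative")
  expect_error(simConfig(nFrames = 1), "nFrames")
  expect_error(simConfig(f0Baseline = NaN), "finite")
  expect_error(simulatePopulation(simConfig(nCells = 2)), "seed")
})

test_that("a noiseless movie reproduces traces by footprint means", {
  sim <- simulatePopulation(quietConfig(nCells = 1,
                            classProportions = c(1, 0, 0, 0)), seed = 2)
  sim <- simulateMovie(sim, height = 48, width = 48, cellRadius = 4,
                       noiseSd = 0, seed = 3)
  ext <- extractTraces(simMovie(sim), trueMask(sim))
  expect_equal(unname(rawTraces(ext)[1, ]),
               unname(rawTraces(simTraces(sim))[1, ]), tolerance = 1e-9)
})

test_that("a zero-cell movie is pure background with an empty mask", {
  cfg <- simConfig(nCells = 0)
  sim <- simulatePopulation(cfg, seed = 1)
  sim <- simulateMovie(sim, height = 32, width = 32, noiseSd = 0, seed = 1)
  expect_identical(nLabels(trueMask(sim)), 0L)
  expect_equal(max(movieData(simMovie(sim))) - min(movieData(simMovie(sim))), 0)
})

test_that("footprints of distinct cells are pairwise disjoint", {
  cfg <- simConfig(nCells = 50, classProportions = c(1/3, 1/3, 1/3, 0))
  sim <- simulatePopulation(cfg, seed = 9)
  sim <- simulateMovie(sim, height = 256, width = 256, cellRadius = 5,
                       seed = 10)
  rois <- roiTable(trueMask(sim))
  expect_identical(nrow(rois), 50L)
  d <- as.matrix(dist(rois[, c("centroid_row", "centroid_col")]))
  diag(d) <- Inf
  expect_gt(min(d), 2 * 5)
  # footprints disjoint <=> every pixel carries at most one label: total
  # labelled area equals the sum of per-cell footprint areas
  expect_identical(sum(labelMatrix(trueMask(sim)) > 0), sum(rois$area_px))
})

test_that("a movie too small for the population raises a geometry error", {
  sim <- simulatePopulation(simConfig(nCells = 30), seed = 1)
  expect_error(simulateMovie(sim, height = 32, width = 32, cellRadius = 5,
                             seed = 1, maxTries = 50),
               "non-overlapping")
})

test_that("noise-free qPCR simulation encodes folds in Ct differences", {
  # fold 2 -> exactly one cycle earlier; fold 1 -> identical Ct
  tab <- simulateQpcr(c(GENE2 = 2, GENE1 = 1), nReplicates = 3,
                      ctNoiseSd = 0, seed = 1)
  ctOf <- function(g, cond) tab$ct[tab$gene == g & tab$condition == cond]
  expect_equal(unique(ctOf("GENE2", "no_stress") - ctOf("GENE2", "hypoxia")), 1)
  expect_equal(ctOf("GENE1", "no_stress"), ctOf("GENE1", "hypoxia"))
  # closed form: ddCt = -log2(fold) for the CXCR4-like fold 6.89
  tab2 <- simulateQpcr(c(CXCR4 = 6.89), ctNoiseSd = 0, seed = 1)
  dct <- function(cond) {
    mean(tab2$ct[tab2$gene == "CXCR4" & tab2$condition == cond]) -
      mean(tab2$ct[tab2$gene == "ACTB" & tab2$condition == cond])
  }
  expect_equal(dct("hypoxia") - dct("no_stress"), -log2(6.89),
               tolerance = 1e-12)
  expect_error(simulateQpcr(c(A = -2)), "fold")
})

test_that("noise-free viability plates encode the configured percentages", {
  p <- simulateViability(c("150" = 100), blankAbs = 0.1, controlAbs = 1.1,
                         noiseSd = 0, seed = 1)
  expect_equal(unique(p$absorbance[p$role == "treated"]), 1.1)
  p0 <- simulateViability(c("250" = 0), blankAbs = 0.1, controlAbs = 1.1,
                          noiseSd = 0, seed = 1)
  expect_equal(unique(p0$absorbance[p0$role == "treated"]), 0.1)
  # arithmetic oracle: blank + pct/100 * (control - blank)
  p62 <- simulateViability(c("150" = 62.33), blankAbs = 0.1, controlAbs = 1.1,
                           noiseSd = 0, seed = 1)
  expect_equal(unique(p62$absorbance[p62$role == "treated"]), 0.7233,
               tolerance = 1e-12)
  expect_error(simulateViability(c("150" = 50), blankAbs = 1, controlAbs = 0.5),
               "exceed")
})
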