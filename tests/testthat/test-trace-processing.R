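test_that("fitBleachTrend recovers exact and noisy quadratics", {
  t <- seq(0, 590, by = 10)
  cf <- fitBleachTrend(100 - 0.1 * t + 1e-4 * t^2, t)
  expect_equal(unname(cf), c(100, -0.1, 1e-4), tolerance = 1e-6)
  cf0 <- fitBleachTrend(rep(50, 60), t)
  expect_equal(unname(cf0), c(50, 0, 0), tolerance = 1e-9)
  expect_error(fitBleachTrend(c(1, 2)), "3 frames")
  # normal-equations oracle on a noisy quadratic
  set.seed(1)
  y <- 80 - 0.05 * t + 5e-5 * t^2 + rnorm(60)
  X <- cbind(1, t, t^2)
  oracle <- solve(t(X) %*% X, t(X) %*% y)[, 1]
  expect_equal(unname(fitBleachTrend(y, t)), unname(oracle), tolerance = 1e-8)
})

test_that("divisive bleach correction flattens pure decay", {
  t <- seq(0, 590, by = 10)
  flat <- correctBleach(rep(100, 60), t)
  expect_equal(flat$corrected, rep(100, 60), tolerance = 1e-9)
  # the product expands to a cubic whose t^3 cross-term (-2.5e-10 t^3,
  # about 5% of baseline at t = 590) cannot be absorbed by a quadratic;
  # the least-squares residual floor is just above 0.5% of baseline
  decay <- 100 * (1 - 5e-4 * t) * (1 + 5e-7 * t^2)
  corr <- correctBleach(decay, t)$corrected
  expect_true(all(abs(corr - 100) / 100 < 0.006))
  # a purely quadratic multiplicative decay is removed essentially exactly
  quad <- 100 * (1 - 4e-4 * t + 1e-7 * t^2)
  expect_equal(correctBleach(quad, t)$corrected, rep(100, 60),
               tolerance = 1e-9)
  # a trend fitted through zero triggers the subtractive fallback
  crash <- seq(100, -20, length.out = 60)
  expect_warning(res <- correctBleach(pmax(crash, 0), t), "subtractive")
  expect_true(all(is.finite(res$corrected)))
})

test_that("bleach correction preserves detected spike counts", {
  cfg <- quietConfig(nCells = 60, classProportions = c(0.3, 0.4, 0.3, 0))
  clean <- simulatePopulation(cfg, seed = 8)
  cfgB <- simConfig(nCells = 60, classProportions = c(0.3, 0.4, 0.3, 0),
                    noiseSd = 0, bleachCoefs = c(-4e-4, 1e-7))
  bleached <- simulatePopulation(cfgB, seed = 8)   # same seed: same events
  nClean <- computeFeatures(normalizeTraces(simTraces(clean)))$spike_count
  nBleached <- computeFeatures(normalizeTraces(simTraces(bleached)))$spike_count
  expect_gte(mean(nClean == nBleached), 0.95)
})

test_that("computeDff matches the definitional examples", {
  r <- computeDff(c(100, 100, 200, 100), baselineQuantile = 0)
  expect_equal(r$dff, c(0, 0, 1, 0))
  expect_equal(r$f0, 100)
  expect_equal(computeDff(rep(7, 10))$dff, rep(0, 10))
  expect_error(computeDff(rep(0, 10)), "baseline")
  # ratio identity: scaling leaves deltaF/F0 unchanged
  x <- c(90, 100, 150, 95, 100, 210, 100)
  expect_equal(computeDff(x * 3.7)$dff, computeDff(x)$dff, tolerance = 1e-10)
})

test_that("the full normalisation chain is scale invariant", {
  sim <- simulatePopulation(simConfig(nCells = 30), seed = 14)
  ts <- simTraces(sim)
  base <- normalizeTraces(ts)
  spikesBase <- detectSpikes(base)
  featBase <- computeFeatures(base, spikesBase)
  for (c_ in c(0.1, 3, 10)) {
    scaled <- TraceSet(rawTraces(ts) * c_, frameInterval(ts),
                       cellIds(ts), conditionLabel(ts))
    nts <- normalizeTraces(scaled)
    expect_equal(dff(nts), dff(base), tolerance = 1e-10)
    sp <- detectSpikes(nts)
    expect_identical(sp$frame, spikesBase$frame)
    expect_equal(sp$amplitude, spikesBase$amplitude, tolerance = 1e-10)
    ft <- computeFeatures(nts, sp)
    expect_identical(ft$spike_count, featBase$spike_count)
    expect_equal(ft$ca_max, featBase$ca_max, tolerance = 1e-10)
  }
})

test_that("detectSpikes handles flat, single-peak and threshold cases", {
  expect_identical(nrow(detectSpikes(rep(0, 30))), 0L)
  tri <- c(rep(0, 29), seq(0, 1, length.out = 2), seq(0.8, 0, length.out = 5),
           rep(0, 24))
  s <- detectSpikes(tri)
  expect_identical(s$frame, 31L)
  expect_equal(s$amplitude, 1)
  expect_equal(s$time_s, 300)
  # sub-threshold peaks are rejected
  small <- c(rep(0, 10), 0.15, rep(0, 10))
  expect_identical(nrow(detectSpikes(small)), 0L)
  # close peaks: the larger wins within the separation window
  two <- c(rep(0, 5), 0.8, 0.5, 0.9, rep(0, 5))
  s2 <- detectSpikes(two, minSeparation = 3)
  expect_identical(s2$frame, 8L)
  expect_error(detectSpikes(c(0, NA, 1)), "finite")
})

test_that("spike detection recovers simulated ground truth", {
  # bleach-free scenario isolating the detector at deltaF/F0 noise ~0.05;
  # bleach robustness is covered separately above
  cfg <- simConfig(nCells = 200,
                   ampMean = c(0.9, 0.8, 0.7, 0),
                   ampSd = c(0.15, 0.1, 0.1, 0),
                   noiseSd = 5, bleachCoefs = c(0, 0))
  sim <- simulatePopulation(cfg, seed = 17)
  nts <- normalizeTraces(simTraces(sim))
  ft <- computeFeatures(nts)
  truth <- groundTruth(sim)$true_spike_count
  expect_gte(mean(ft$spike_count == truth), 0.95)
  # Ca2+max is at least the largest true event amplitude minus noise slack
  amax <- vapply(as.list(groundTruth(sim)$amplitudes),
                 function(a) if (length(a)) max(a) else 0, numeric(1))
  expect_gte(mean(ft$ca_max >= amax - 3 * 0.05), 0.99)
})

test_that("features and raster conserve spike counts", {
  sim <- simulatePopulation(simConfig(nCells = 25), seed = 19)
  nts <- normalizeTraces(simTraces(sim))
  sp <- detectSpikes(nts)
  ft <- computeFeatures(nts, sp)
  raster <- buildRaster(sp, cellIds = cellIds(nts))
  expect_identical(nrow(raster), nrow(sp))                     # one mark/spike
  marks <- table(factor(raster$cell_id, levels = cellIds(nts)))
  expect_identical(as.integer(marks), ft$spike_count)
  expect_equal(raster$time_s, (raster$frame - 1) * 10)
  # empty raster keeps the population size
  empty <- buildRaster(sp[0, ], cellIds = cellIds(nts))
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "nCells"), length(cellIds(nts)))
})

test_that("computeFeatures reports whole-trace maxima", {
  sim <- simulatePopulation(silentConfig(), seed = 1)
  nts <- normalizeTraces(simTraces(sim))
  ft <- computeFeatures(nts)
  expect_identical(ft$spike_count, 0L)
  expect_gte(ft$ca_max, 0)
})
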