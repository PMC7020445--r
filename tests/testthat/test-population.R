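test_that("k-means recovers four well-separated synthetic blobs exactly", {
  skip_if_not_installed("mclust")
  # idealised blobs, one tight cluster per activity class
  set.seed(77)
  blob <- function(n, s, a, js, ja) {
    data.frame(spike_count = s + sample(0:js, n, replace = TRUE),
               ca_max = a + runif(n, -ja, ja))
  }
  feats <- rbind(blob(20, 10, 1.2, 3, 0.1), blob(40, 3, 0.8, 2, 0.05),
                 blob(60, 2, 0.25, 2, 0.05), blob(30, 0, 0.05, 0, 0.02))
  feats$cell_id <- sprintf("c%03d", seq_len(nrow(feats)))
  truth <- rep(activityClasses(), c(20, 40, 60, 30))
  model <- clusterFeatures(feats, k = 4, seed = 1)
  expect_equal(mclust::adjustedRandIndex(clusterAssignments(model), truth), 1)
  mapping <- nameClusters(model)
  pred <- mapping[as.character(clusterAssignments(model)[feats$cell_id])]
  expect_true(all(pred == truth))
})

test_that("clustering of the control preset recovers generating classes", {
  f <- simFeatures("control", seed = 101)
  model <- clusterFeatures(f$features, k = 4, seed = 1)
  mapping <- nameClusters(model)
  pred <- mapping[as.character(clusterAssignments(model)[f$features$cell_id])]
  expect_gte(mean(pred == f$truth$true_class), 0.9)
})

test_that("clustering is deterministic and degrades gracefully", {
  f <- simFeatures("control", seed = 102, nCells = 60)
  m1 <- clusterFeatures(f$features, k = 4, seed = 9)
  m2 <- clusterFeatures(f$features, k = 4, seed = 9)
  expect_identical(clusterAssignments(m1), clusterAssignments(m2))
  expect_equal(clusterCentroids(m1), clusterCentroids(m2))
  # all-identical points: k collapses to a single cluster at that point
  ident <- data.frame(cell_id = paste0("c", 1:10),
                      spike_count = rep(3L, 10), ca_max = rep(0.4, 10))
  expect_warning(m3 <- clusterFeatures(ident, k = 4, seed = 1), "distinct")
  expect_identical(m3@k, 1L)
  expect_equal(unname(clusterCentroids(m3)[1, ]), c(3, 0.4))
  expect_error(clusterFeatures(ident[1:2, ], k = 4), "fewer cells")
})

test_that("boundary classification follows the published rules", {
  b <- ClassBoundaries()
  expect_identical(classifyCell(7, 1.2, b), "hyperactive")
  expect_identical(classifyCell(3, 0.8, b), "moderate")
  expect_identical(classifyCell(2, 0.3, b), "low")
  expect_identical(classifyCell(0, 0.1, b), "silent")
  # boundary values: exactly 6 spikes is not hyperactive
  expect_identical(classifyCell(6, 1.0, b), "moderate")
  expect_error(classifyCell(-1, 0.5, b), "non-negative")
  # totality on a grid of feature values
  grid <- expand.grid(s = 0:12, a = seq(0, 1.5, by = 0.25))
  cls <- classifyCell(grid$s, grid$a, b)
  expect_true(all(cls %in% activityClasses()))
})

test_that("nameClusters maps centroids and resolves the low/silent pair", {
  mk <- function(centroids) {
    new("ClusterModel", k = nrow(centroids),
        centroids = matrix(centroids, ncol = 2,
                           dimnames = list(NULL, c("spike_count", "ca_max"))),
        scaling = list(min = c(0, 0), max = c(1, 1)),
        assignments = integer(0), totWithinSS = 0, seed = 1L, nRestarts = 1L)
  }
  m <- mk(rbind(c(9, 1.3), c(3, 0.9), c(2, 0.2), c(0, 0.05)))
  expect_identical(unname(nameClusters(m)),
                   c("hyperactive", "moderate", "low", "silent"))
  # two lower-activity clusters: lower spike count becomes silent
  m2 <- mk(rbind(c(9, 1.3), c(3, 0.9), c(2, 0.2), c(1, 0.1)))
  expect_identical(unname(nameClusters(m2)),
                   c("hyperactive", "moderate", "low", "silent"))
  # all centroids above the spike threshold: ambiguity is reported, kept
  m3 <- mk(rbind(c(8, 1), c(9, 1.1), c(10, 1.2), c(12, 1.3)))
  expect_warning(cls3 <- nameClusters(m3), "ambiguous")
  expect_true(all(cls3 == "hyperactive"))
})

test_that("derived boundaries are midpoints with documented fallbacks", {
  f <- data.frame(cell_id = paste0("c", 1:6),
                  spike_count = c(8L, 9L, 5L, 4L, 2L, 0L),
                  ca_max = c(1.2, 1.3, 0.9, 0.8, 0.3, 0.05))
  model <- new("ClusterModel", k = 4L,
               centroids = matrix(c(8.5, 4.5, 2, 0, 1.25, 0.85, 0.3, 0.05),
                                  4, 2,
                                  dimnames = list(NULL,
                                                  c("spike_count", "ca_max"))),
               scaling = list(min = c(0, 0), max = c(1, 1)),
               assignments = setNames(c(1L, 1L, 2L, 2L, 3L, 4L), f$cell_id),
               totWithinSS = 0, seed = 1L, nRestarts = 1L)
  mapping <- setNames(c("hyperactive", "moderate", "low", "silent"), 1:4)
  b <- suppressMessages(deriveBoundaries(model, mapping, f))
  expect_equal(b@spikeThr, (5 + 8) / 2)       # moderate max 5, hyper min 8
  expect_equal(b@ampThr, (0.8 + 0.3) / 2)     # moderate min, low max
  # a missing hyperactive class falls back to the published default of 6
  mapping2 <- setNames(c("moderate", "moderate", "low", "silent"), 1:4)
  expect_warning(b2 <- suppressMessages(deriveBoundaries(model, mapping2, f)),
                 "falling back")
  expect_equal(b2@spikeThr, 6)
})

test_that("boundary classification agrees with clustering on control data", {
  f <- simFeatures("control", seed = 103)
  model <- clusterFeatures(f$features, k = 4, seed = 3)
  mapping <- nameClusters(model)
  b <- suppressMessages(deriveBoundaries(model, mapping, f$features))
  viaBoundary <- classifyCells(f$features, b)
  viaCluster <- mapping[as.character(clusterAssignments(model)[f$features$cell_id])]
  expect_gte(mean(viaBoundary == viaCluster), 0.95)
})

test_that("subsampled profiles are conserved and unbiased", {
  f <- simFeatures("control", seed = 104)
  b <- ClassBoundaries()
  prof <- subsampleProfiles(f$features, b, seed = 5)
  expect_identical(nrow(prof), 5L)
  expect_equal(rowSums(prof[activityClasses()]), rep(100, 5),
               tolerance = 1e-9)
  expect_s3_class(attr(prof, "summary"), "data.frame")
  # all-hyperactive population: every profile is (100, 0, 0, 0)
  hyper <- data.frame(cell_id = paste0("c", 1:20),
                      spike_count = 10L, ca_max = 1.2, condition = "x")
  ph <- subsampleProfiles(hyper, b, sampleSize = 10, seed = 1)
  expect_true(all(ph$hyperactive == 100))
  expect_true(all(ph[c("moderate", "low", "silent")] == 0))
  expect_error(subsampleProfiles(hyper, b, sampleSize = 50), "exceeds")
  # resampling consistency: the mean of many subsample profiles approaches
  # the full-population profile (brute-force oracle over 200 repeats)
  full <- classProfile(f$features, b)
  many <- subsampleProfiles(f$features, b, nRepeats = 200, seed = 6)
  for (cl in activityClasses()) {
    se <- sd(many[[cl]]) / sqrt(200)
    expect_lt(abs(mean(many[[cl]]) - full[[cl]]), 3 * se + 1e-9)
  }
})

test_that("condition comparisons detect shifts and respect ties", {
  f <- simFeatures("control", seed = 105)
  h <- simFeatures("hypoxia", seed = 106)
  b <- ClassBoundaries()
  prof <- rbind(subsampleProfiles(f$features, b, seed = 7),
                subsampleProfiles(h$features, b, seed = 8))
  res <- compareConditions(prof)
  expect_identical(res$class, activityClasses())
  hyp <- res[res$class == "hyperactive", ]
  expect_true(hyp$significant)
  # identical profile sets in both conditions: perfect rank balance, p = 1
  p1 <- subsampleProfiles(f$features, b, seed = 9)
  p2 <- p1; p2$condition <- "copy"; p2$sample_id <- paste0("copy", 1:5)
  same <- compareConditions(rbind(p1, p2))
  expect_equal(same$p, rep(1, 4))
  expect_error(compareConditions(p1), "two conditions")
  short <- rbind(p1, p2[1, ])
  expect_error(compareConditions(short), ">= 2 profiles")
})

test_that("hypoxia preset shifts subpopulations in the reported direction", {
  f <- simFeatures("control", seed = 107)
  h <- simFeatures("hypoxia", seed = 108)
  b <- ClassBoundaries()
  pc <- classProfile(f$features, b)
  ph <- classProfile(h$features, b)
  expect_gt(ph[["hyperactive"]], pc[["hyperactive"]])
  expect_gt(ph[["moderate"]], pc[["moderate"]])
  expect_lt(ph[["low"]], pc[["low"]])
})
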