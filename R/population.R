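#' k-means clustering of (spike count, Ca2+max) features
#'
#' Features are min-max scaled to [0, 1] per dimension (counts and amplitudes
#' differ in scale by an order of magnitude, and unscaled Euclidean k-means
#' would be count-dominated), then clustered with k-means using k-means++
#' initialisation and \code{nRestarts} restarts, keeping the solution with the
#' lowest within-cluster sum of squares. Deterministic for a given seed.
#'
#' @param features feature table from \code{\link{computeFeatures}} (columns
#'   cell_id, spike_count, ca_max).
#' @param k number of clusters (default 4, the four activity classes of a
#'   control population).
#' @param seed integer seed.
#' @param nRestarts number of k-means++ restarts (default 50).
#' @return A \linkS4class{ClusterModel} with centroids in raw feature units.
#' @export
clusterFeatures <- function(features, k = 4, seed = 1L, nRestarts = 50L) {
  X <- as.matrix(features[, c("spike_count", "ca_max")])
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("clusterFeatures: features must be finite")
  if (nrow(X) < k) stop("clusterFeatures: fewer cells than clusters")
  nDistinct <- nrow(unique(X))
  if (nDistinct < k) {
    warning("clusterFeatures: only ", nDistinct,
            " distinct feature points; reducing k from ", k)
    k <- nDistinct
  }
  k <- as.integer(k)
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  span <- ifelse(hi > lo, hi - lo, 1)
  Xs <- sweep(sweep(X, 2L, lo), 2L, span, "/")
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(nRestarts)) {
      centers <- .kmeansPlusPlusInit(Xs, k)
      fit <- tryCatch(
        stats::kmeans(Xs, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) {
          suppressWarnings(stats::kmeans(Xs, centers = centers,
                                         iter.max = 200L,
                                         algorithm = "Lloyd"))
        })
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop("clusterFeatures: k-means failed on every restart")
  centroids <- sweep(sweep(best$centers, 2L, span, "*"), 2L, lo, "+")
  colnames(centroids) <- c("spike_count", "ca_max")
  new("ClusterModel", k = k, centroids = centroids,
      scaling = list(min = lo, max = hi),
      assignments = stats::setNames(as.integer(best$cluster),
                                    features$cell_id),
      totWithinSS = best$tot.withinss, seed = as.integer(seed),
      nRestarts = as.integer(nRestarts))
}

# k-means++ seeding: first center uniform, then points weighted by squared
# distance to the nearest chosen center
.kmeansPlusPlusInit <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  for (j in 2L:k) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1L, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers + stats::runif(length(centers), 0, 1e-10)  # break exact duplicates
}

#' Classify cells into activity classes from boundary rules
#'
#' Applies the axis-aligned boundary rules: spike count above
#' \code{spikeThr} makes a cell hyperactive; otherwise Ca2+max above
#' \code{ampThr} with at least one spike makes it moderate; otherwise a spike
#' count of at most \code{silentMaxSpikes} makes it silent; the remainder are
#' low activity. A total function over finite non-negative features.
#'
#' @param spikeCount numeric vector of spike counts (>= 0).
#' @param caMax numeric vector of Ca2+max values (>= 0).
#' @param boundaries a \linkS4class{ClassBoundaries}.
#' @return character vector of activity classes.
#' @export
#' @examples
#' classifyCell(c(7, 3, 2, 0), c(1.2, 0.8, 0.3, 0.1), ClassBoundaries())
classifyCell <- function(spikeCount, caMax, boundaries = ClassBoundaries()) {
  if (any(!is.finite(spikeCount)) || any(!is.finite(caMax)) ||
      any(spikeCount < 0) || any(caMax < 0))
    stop("classifyCell: features must be finite and non-negative")
  out <- ifelse(spikeCount > boundaries@spikeThr, "hyperactive",
         ifelse(caMax > boundaries@ampThr & spikeCount >= 1, "moderate",
         ifelse(spikeCount <= boundaries@silentMaxSpikes, "silent", "low")))
  unname(out)
}

#' @rdname classifyCell
#' @param features feature table with columns spike_count and ca_max.
#' @export
classifyCells <- function(features, boundaries = ClassBoundaries()) {
  classifyCell(features$spike_count, features$ca_max, boundaries)
}

#' Name k-means clusters with activity classes
#'
#' Each centroid (in raw feature units) is classified with the boundary
#' rules. When two clusters receive the same lower-activity class, the pair
#' is split into low and silent by centroid spike count (the lower becomes
#' silent). Any other duplication is reported as an ambiguity warning and
#' kept, resolved only in the low/silent case; the mapping is always total.
#'
#' @param model a \linkS4class{ClusterModel}.
#' @param boundaries a \linkS4class{ClassBoundaries}.
#' @return character vector of length k: cluster index -> activity class.
#' @export
nameClusters <- function(model, boundaries = ClassBoundaries()) {
  ctr <- clusterCentroids(model)
  classes <- classifyCell(ctr[, "spike_count"], ctr[, "ca_max"], boundaries)
  for (cl in c("low", "silent")) {
    dup <- which(classes == cl)
    if (length(dup) == 2L) {
      ord <- dup[order(ctr[dup, "spike_count"])]
      classes[ord[1L]] <- "silent"
      classes[ord[2L]] <- "low"
    } else if (length(dup) > 2L) {
      warning("nameClusters: ", length(dup), " clusters classify as '", cl,
              "'; keeping centroid ordering (lowest spike count -> silent)")
      ord <- dup[order(ctr[dup, "spike_count"])]
      classes[ord[1L]] <- "silent"
      classes[ord[-1L]] <- "low"
    }
  }
  for (cl in c("hyperactive", "moderate")) {
    if (sum(classes == cl) > 1L)
      warning("nameClusters: ", sum(classes == cl),
              " clusters classify as '", cl, "' (ambiguous mapping)")
  }
  stats::setNames(classes, seq_len(model@k))
}

#' Derive activity-class boundaries from a named control clustering
#'
#' The spike-count threshold is the midpoint between the maximum spike count
#' among cells of moderate-named clusters and the minimum spike count in the
#' hyperactive cluster; the Ca2+max threshold is the midpoint between the
#' moderate minimum and the low maximum. When a class is missing the
#' corresponding default (6 spikes, 0.5 deltaF/F0) is used, with a warning.
#' The derived values are reported via \code{message}.
#'
#' @param model a fitted \linkS4class{ClusterModel}.
#' @param mapping cluster -> class mapping from \code{\link{nameClusters}}.
#' @param features the feature table the model was fitted on.
#' @return A \linkS4class{ClassBoundaries}.
#' @export
deriveBoundaries <- function(model, mapping, features) {
  assign <- clusterAssignments(model)
  cellClass <- mapping[as.character(assign[features$cell_id])]
  spikeThr <- 6
  modCounts <- features$spike_count[cellClass == "moderate"]
  hypCounts <- features$spike_count[cellClass == "hyperactive"]
  if (length(modCounts) && length(hypCounts)) {
    spikeThr <- (max(modCounts) + min(hypCounts)) / 2
  } else {
    warning("deriveBoundaries: moderate or hyperactive cluster missing; ",
            "falling back to spikeThr = 6")
  }
  ampThr <- 0.5
  modAmp <- features$ca_max[cellClass == "moderate"]
  lowAmp <- features$ca_max[cellClass == "low"]
  if (length(modAmp) && length(lowAmp)) {
    ampThr <- (min(modAmp) + max(lowAmp)) / 2
  } else {
    warning("deriveBoundaries: moderate or low cluster missing; ",
            "falling back to ampThr = 0.5")
  }
  if (spikeThr <= 0) spikeThr <- 6
  if (ampThr <= 0) ampThr <- 0.5
  message(sprintf("deriveBoundaries: spikeThr = %.3f, ampThr = %.3f",
                  spikeThr, ampThr))
  ClassBoundaries(spikeThr = spikeThr, ampThr = ampThr)
}

#' Full-population subpopulation profile
#'
#' @param features feature table.
#' @param boundaries a \linkS4class{ClassBoundaries}.
#' @return named numeric: percentage of cells per activity class (sums to 100).
#' @export
classProfile <- function(features, boundaries = ClassBoundaries()) {
  cls <- factor(classifyCells(features, boundaries),
                levels = activityClasses())
  pct <- 100 * as.vector(table(cls)) / nrow(features)
  stats::setNames(pct, activityClasses())
}

#' Subsampled subpopulation profiles
#'
#' Draws \code{nRepeats} random subsamples without replacement (size
#' \code{sampleSize} when given, else \code{round(fraction * n)}), classifies
#' each draw with the boundary rules and converts class counts to
#' percentages. The mean and SEM across draws are attached as attribute
#' \code{"summary"}. Defaults mirror an unbiased selection of 90 cells from a
#' population of 160, repeated five times.
#'
#' @param features feature table with a condition column.
#' @param boundaries a \linkS4class{ClassBoundaries}.
#' @param fraction fraction of cells per draw (default 0.6), used when
#'   \code{sampleSize} is NULL.
#' @param sampleSize cells per draw (default 90; takes precedence over
#'   \code{fraction}; set NULL to use the fraction).
#' @param nRepeats number of draws (default 5).
#' @param seed integer seed.
#' @return data.frame with columns sample_id, condition and one percentage
#'   column per activity class; attribute "summary" holds per-class mean and
#'   SEM.
#' @export
subsampleProfiles <- function(features, boundaries = ClassBoundaries(),
                              fraction = 0.6, sampleSize = 90,
                              nRepeats = 5L, seed = 1L) {
  n <- nrow(features)
  size <- if (!is.null(sampleSize)) sampleSize else round(fraction * n)
  if (size > n)
    stop("subsampleProfiles: sample size (", size,
         ") exceeds the population (", n, ")")
  cond <- if ("condition" %in% names(features))
    as.character(features$condition[1L]) else NA_character_
  withr::with_seed(as.integer(seed), {
    profs <- lapply(seq_len(nRepeats), function(i) {
      idx <- sample.int(n, size)
      p <- classProfile(features[idx, , drop = FALSE], boundaries)
      cbind(data.frame(sample_id = sprintf("%s_rep%d", cond, i),
                       condition = cond), as.data.frame(as.list(p)))
    })
    out <- do.call(rbind, profs)
    m <- colMeans(out[activityClasses()])
    sem <- apply(out[activityClasses()], 2L, stats::sd) / sqrt(nRepeats)
    attr(out, "summary") <- data.frame(class = activityClasses(),
                                       mean = as.numeric(m),
                                       sem = as.numeric(sem))
    out
  })
}

#' Compare subpopulation percentages across conditions
#'
#' Kruskal-Wallis test on the per-repeat class percentages across conditions,
#' one test per activity class, at significance level 0.05. Subsample repeats
#' are the replication unit.
#'
#' @param profiles profile table from \code{\link{subsampleProfiles}} (rows
#'   from two or more conditions bound together).
#' @param classes activity classes to test (default all four).
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns class, H, p, significant.
#' @export
compareConditions <- function(profiles, classes = activityClasses(),
                              alpha = 0.05) {
  conds <- unique(profiles$condition)
  if (length(conds) < 2L)
    stop("compareConditions: at least two conditions are required")
  sizes <- table(profiles$condition)
  if (any(sizes < 2L))
    stop("compareConditions: every condition needs >= 2 profiles (got ",
         paste(sizes, collapse = ", "), ")")
  res <- lapply(classes, function(cl) {
    kw <- kruskalWallis(split(profiles[[cl]], profiles$condition))
    data.frame(class = cl, H = kw$H, p = kw$p, significant = kw$p < alpha)
  })
  do.call(rbind, res)
}
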