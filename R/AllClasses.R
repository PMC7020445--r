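#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- colData
NULL

#' Activity classes of calcium spiking
#'
#' The four activity classes used throughout the package, in decreasing order
#' of activity: hyperactive, moderate, low and silent. Cells are assigned to a
#' class from their spike count per recording and their maximum deltaF/F0
#' (Ca2+max).
#'
#' @return Character vector of the four class names.
#' @export
#' @examples
#' activityClasses()
activityClasses <- function() c("hyperactive", "moderate", "low", "silent")

#' Conventional display colours of the activity classes
#'
#' @return Named character vector mapping class to colour
#'   (red/green/black/cyan).
#' @export
classColors <- function() {
  c(hyperactive = "red", moderate = "green3", low = "black", silent = "cyan3")
}

# ---------------------------------------------------------------------------
# CaMovie
# ---------------------------------------------------------------------------

#' CaMovie: a time-lapse fluorescence movie
#'
#' Container for a single-channel time-lapse stack, stored as a 3D array of
#' dimension frames x height x width, together with the acquisition frame
#' interval in seconds (default 10 s, i.e. 60 frames over a 600 s recording).
#'
#' @slot data numeric array, frames x height x width, non-negative finite
#'   intensities.
#' @slot frameInterval numeric(1), seconds between frames.
#' @export
setClass("CaMovie",
  representation(data = "array", frameInterval = "numeric"))

setValidity("CaMovie", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array (frames x height x width)")
  if (dim(d)[1L] < 2L) return("a movie needs at least 2 frames")
  if (!all(is.finite(d))) return("movie intensities must be finite")
  if (min(d) < 0) return("movie intensities must be non-negative")
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    return("frameInterval must be a single positive number")
  TRUE
})

#' Construct a CaMovie
#'
#' @param data 3D numeric array, frames x height x width.
#' @param frameInterval seconds between frames (default 10).
#' @return A \linkS4class{CaMovie}.
#' @export
CaMovie <- function(data, frameInterval = 10) {
  new("CaMovie", data = data, frameInterval = frameInterval)
}

#' @describeIn CaMovie-class number of frames
#' @param x,object a CaMovie
#' @export
setMethod("length", "CaMovie", function(x) dim(x@data)[1L])

setMethod("show", "CaMovie", function(object) {
  d <- dim(object@data)
  cat(sprintf("CaMovie: %d frames, %d x %d px, dt = %g s (duration %g s)\n",
              d[1L], d[2L], d[3L], object@frameInterval,
              (d[1L] - 1L) * object@frameInterval))
})

#' Movie pixel data
#' @param x a \linkS4class{CaMovie}
#' @return the frames x height x width array
#' @export
movieData <- function(x) {
  stopifnot(is(x, "CaMovie"))
  x@data
}

# ---------------------------------------------------------------------------
# LabelMask
# ---------------------------------------------------------------------------

#' LabelMask: an integer-labelled segmentation mask
#'
#' A height x width integer image in which 0 is background and 1..n index the
#' segmented cells. Labels are contiguous from 1.
#'
#' @slot labels integer matrix, height x width.
#' @export
setClass("LabelMask", representation(labels = "matrix"))

setValidity("LabelMask", function(object) {
  L <- object@labels
  if (!is.numeric(L)) return("labels must be numeric")
  if (any(L < 0) || any(L != floor(L))) return("labels must be non-negative integers")
  n <- max(L)
  if (n > 0 && !all(seq_len(n) %in% L))
    return("label set must be contiguous 1..n")
  TRUE
})

#' Construct a LabelMask
#' @param labels integer matrix (0 = background, 1..n = cells).
#' @return A \linkS4class{LabelMask}.
#' @export
LabelMask <- function(labels) {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels)
}

#' Number of labelled cells in a mask
#' @param mask a \linkS4class{LabelMask}
#' @export
nLabels <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  max(0L, max(mask@labels))
}

#' Label matrix of a mask
#' @param mask a \linkS4class{LabelMask}
#' @export
labelMatrix <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  mask@labels
}

#' Per-label region table
#'
#' @param mask a \linkS4class{LabelMask}
#' @return data.frame with columns label, area_px, centroid_row, centroid_col
#'   (0-based pixel coordinates, (row, col) convention).
#' @export
roiTable <- function(mask) {
  L <- labelMatrix(mask)
  n <- nLabels(mask)
  if (n == 0L) {
    return(data.frame(label = integer(0), area_px = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  }
  idx <- which(L > 0)
  lab <- L[idx]
  rows <- (idx - 1L) %% nrow(L)          # 0-based
  cols <- (idx - 1L) %/% nrow(L)
  area <- tabulate(lab, nbins = n)
  data.frame(label = seq_len(n),
             area_px = area,
             centroid_row = as.numeric(tapply(rows, lab, mean)),
             centroid_col = as.numeric(tapply(cols, lab, mean)))
}

setMethod("show", "LabelMask", function(object) {
  cat(sprintf("LabelMask: %d x %d px, %d cells\n",
              nrow(object@labels), ncol(object@labels), nLabels(object)))
})

# ---------------------------------------------------------------------------
# TraceSet / NormalizedTraceSet
# ---------------------------------------------------------------------------

#' TraceSet: per-cell fluorescence time courses
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"raw"} holding the
#' cells x frames intensity matrix. Column data carry the time of each frame in
#' seconds; metadata carry the frame interval and an optional condition label.
#'
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

setValidity("TraceSet", function(object) {
  if (!"raw" %in% names(assays(object))) return("TraceSet needs a 'raw' assay")
  raw <- assay(object, "raw")
  if (ncol(raw) < 2L) return("a TraceSet needs at least 2 frames")
  if (nrow(raw) > 0 && (!all(is.finite(raw)) || min(raw) < 0))
    return("raw intensities must be finite and non-negative")
  if (is.null(metadata(object)$frameInterval))
    return("metadata frameInterval missing")
  TRUE
})

#' Construct a TraceSet
#'
#' @param raw cells x frames numeric matrix of raw fluorescence.
#' @param frameInterval seconds between frames (default 10).
#' @param cellIds optional character vector of cell identifiers.
#' @param condition optional condition label (e.g. "control", "hypoxia").
#' @return A \linkS4class{TraceSet}.
#' @export
TraceSet <- function(raw, frameInterval = 10, cellIds = NULL,
                     condition = NA_character_) {
  raw <- as.matrix(raw)
  if (is.null(cellIds)) {
    cellIds <- if (!is.null(rownames(raw))) rownames(raw) else
      sprintf("cell_%03d", seq_len(nrow(raw)))
  }
  rownames(raw) <- cellIds
  times <- (seq_len(ncol(raw)) - 1) * frameInterval
  colnames(raw) <- as.character(times)
  se <- SummarizedExperiment(
    assays = list(raw = raw),
    rowData = DataFrame(cell_id = cellIds, row.names = cellIds),
    colData = DataFrame(time_s = times, row.names = as.character(times)))
  metadata(se)$frameInterval <- frameInterval
  metadata(se)$condition <- condition
  new("TraceSet", se)
}

#' NormalizedTraceSet: bleach-corrected, deltaF/F0-normalised traces
#'
#' Extends \linkS4class{TraceSet} with a \code{"dff"} assay (deltaF/F0), and
#' per-cell row data: the baseline F0 and the fitted quadratic bleach-trend
#' coefficients (a, b, c) of \code{a + b t + c t^2}.
#'
#' @export
setClass("NormalizedTraceSet", contains = "TraceSet")

setValidity("NormalizedTraceSet", function(object) {
  if (!"dff" %in% names(assays(object))) return("needs a 'dff' assay")
  rd <- rowData(object)
  need <- c("f0", "bleach_a", "bleach_b", "bleach_c")
  if (!all(need %in% colnames(rd))) return("rowData must carry f0 and bleach coefficients")
  if (nrow(rd) > 0) {
    if (any(!is.finite(rd$f0)) || any(rd$f0 <= 0)) return("f0 must be positive")
    if (!all(is.finite(assay(object, "dff")))) return("dff must be finite")
  }
  TRUE
})

#' Frame interval of a trace container or movie, in seconds
#' @param x a TraceSet or CaMovie
#' @export
frameInterval <- function(x) {
  if (is(x, "CaMovie")) return(x@frameInterval)
  metadata(x)$frameInterval
}

#' Cell identifiers of a TraceSet
#' @param x a TraceSet
#' @export
cellIds <- function(x) rownames(x)

#' Condition label of a TraceSet
#' @param x a TraceSet
#' @export
conditionLabel <- function(x) metadata(x)$condition

#' Raw trace matrix (cells x frames)
#' @param x a TraceSet
#' @export
rawTraces <- function(x) assay(x, "raw")

#' deltaF/F0 matrix (cells x frames)
#' @param x a NormalizedTraceSet
#' @export
dff <- function(x) assay(x, "dff")

#' Per-cell baseline fluorescence F0
#' @param x a NormalizedTraceSet
#' @export
f0Values <- function(x) setNames(rowData(x)$f0, rownames(x))

#' Per-cell fitted bleach-trend coefficients
#' @param x a NormalizedTraceSet
#' @return matrix with columns a, b, c of the quadratic trend a + b t + c t^2.
#' @export
bleachCoefs <- function(x) {
  rd <- rowData(x)
  m <- cbind(a = rd$bleach_a, b = rd$bleach_b, c = rd$bleach_c)
  rownames(m) <- rownames(x)
  m
}

#' Frame times of a TraceSet, in seconds
#' @param x a TraceSet
#' @export
frameTimes <- function(x) colData(x)$time_s

setMethod("show", "TraceSet", function(object) {
  cat(sprintf("%s: %d cells x %d frames, dt = %g s, condition = %s\n",
              class(object), nrow(object), ncol(object),
              frameInterval(object), conditionLabel(object)))
})

# ---------------------------------------------------------------------------
# ClusterModel / ClassBoundaries
# ---------------------------------------------------------------------------

#' ClusterModel: a fitted k-means model on (spike count, Ca2+max)
#'
#' Centroids are stored in raw feature units; \code{scaling} records the
#' per-feature min/max used to scale features to [0, 1] before fitting.
#'
#' @slot k integer, number of clusters.
#' @slot centroids k x 2 matrix (spike_count, ca_max) in raw units.
#' @slot scaling list with numeric vectors \code{min} and \code{max}.
#' @slot assignments named integer vector, cell id -> cluster index.
#' @slot totWithinSS numeric, best within-cluster sum of squares (scaled space).
#' @slot seed integer seed used.
#' @slot nRestarts integer number of k-means++ restarts.
#' @export
setClass("ClusterModel",
  representation(k = "integer", centroids = "matrix", scaling = "list",
                 assignments = "integer", totWithinSS = "numeric",
                 seed = "integer", nRestarts = "integer"))

setValidity("ClusterModel", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (!all(is.finite(object@centroids))) return("centroids must be finite")
  if (nrow(object@centroids) != object@k) return("centroids must have k rows")
  if (length(object@assignments) &&
      (min(object@assignments) < 1L || max(object@assignments) > object@k))
    return("assignments out of range")
  TRUE
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d, %d cells, tot.withinss = %.4f\n",
              object@k, length(object@assignments), object@totWithinSS))
  print(round(object@centroids, 3))
})

#' Cluster centroids in raw feature units
#' @param model a \linkS4class{ClusterModel}
#' @export
clusterCentroids <- function(model) model@centroids

#' Cluster assignments (cell id -> cluster index)
#' @param model a \linkS4class{ClusterModel}
#' @export
clusterAssignments <- function(model) model@assignments

#' ClassBoundaries: axis-aligned activity-class thresholds
#'
#' The boundary rules of the four activity classes: more than \code{spikeThr}
#' spikes per 600 s recording marks a cell hyperactive; otherwise Ca2+max above
#' \code{ampThr} (with at least one spike) marks it moderate; otherwise cells
#' with at most \code{silentMaxSpikes} spikes are silent and the rest are low
#' activity. Defaults follow the >6 spikes / Ca2+max 0.5 boundaries derived
#' from control cultures.
#'
#' @slot spikeThr numeric, spike-count threshold (default 6).
#' @slot ampThr numeric, Ca2+max threshold in deltaF/F0 units (default 0.5).
#' @slot silentMaxSpikes integer, maximum spikes of a silent cell (default 0).
#' @export
setClass("ClassBoundaries",
  representation(spikeThr = "numeric", ampThr = "numeric",
                 silentMaxSpikes = "integer"))

setValidity("ClassBoundaries", function(object) {
  if (object@spikeThr <= 0) return("spikeThr must be > 0")
  if (object@ampThr <= 0) return("ampThr must be > 0")
  if (object@silentMaxSpikes < 0L) return("silentMaxSpikes must be >= 0")
  TRUE
})

#' Construct ClassBoundaries
#' @param spikeThr spike-count threshold separating hyperactive cells
#'   (default 6, i.e. hyperactive means > 6 spikes per 10 min).
#' @param ampThr Ca2+max threshold separating moderate from low/silent
#'   (default 0.5 deltaF/F0).
#' @param silentMaxSpikes maximum spike count of a silent cell (default 0).
#' @return A \linkS4class{ClassBoundaries}.
#' @export
ClassBoundaries <- function(spikeThr = 6, ampThr = 0.5, silentMaxSpikes = 0L) {
  new("ClassBoundaries", spikeThr = spikeThr, ampThr = ampThr,
      silentMaxSpikes = as.integer(silentMaxSpikes))
}

setMethod("show", "ClassBoundaries", function(object) {
  cat(sprintf(paste0(
    "ClassBoundaries: hyperactive > %g spikes/recording; ",
    "moderate: Ca2+max > %g and >= 1 spike; silent: <= %d spikes; else low\n"),
    object@spikeThr, object@ampThr, object@silentMaxSpikes))
})

# ---------------------------------------------------------------------------
# CaSimulation
# ---------------------------------------------------------------------------

#' CaSimulation: a ground-truthed synthetic dataset
#'
#' Holds the generating configuration, per-cell ground truth (true class,
#' spike frames, event amplitudes), the simulated \linkS4class{TraceSet}, and
#' optionally a simulated \linkS4class{CaMovie} with its true
#' \linkS4class{LabelMask}.
#'
#' @slot config list, the simulation configuration (see \code{\link{simConfig}}).
#' @slot groundTruth a \code{DataFrame} with cell_id, true_class and list
#'   columns spike_frames (1-based frame indices) and amplitudes.
#' @slot traces the simulated \linkS4class{TraceSet}.
#' @slot movie a \linkS4class{CaMovie} or NULL.
#' @slot trueMask a \linkS4class{LabelMask} or NULL.
#' @slot conditionLabel character condition name.
#' @export
setClass("CaSimulation",
  representation(config = "list", groundTruth = "DataFrame",
                 traces = "TraceSet", movie = "ANY", trueMask = "ANY",
                 conditionLabel = "character"))

setMethod("show", "CaSimulation", function(object) {
  tab <- table(factor(object@groundTruth$true_class, levels = activityClasses()))
  cat(sprintf("CaSimulation (%s): %d cells, %d frames%s\n",
              object@conditionLabel, nrow(object@groundTruth),
              ncol(object@traces),
              if (is.null(object@movie)) "" else ", with movie"))
  print(tab)
})

#' Ground-truth table of a simulation
#' @param sim a \linkS4class{CaSimulation}
#' @export
groundTruth <- function(sim) {
  stopifnot(is(sim, "CaSimulation"))
  sim@groundTruth
}

#' Simulated traces of a simulation
#' @param sim a \linkS4class{CaSimulation}
#' @export
simTraces <- function(sim) {
  stopifnot(is(sim, "CaSimulation"))
  sim@traces
}

#' Simulated movie of a simulation (or NULL)
#' @param sim a \linkS4class{CaSimulation}
#' @export
simMovie <- function(sim) {
  stopifnot(is(sim, "CaSimulation"))
  sim@movie
}

#' True label mask of a simulated movie (or NULL)
#' @param sim a \linkS4class{CaSimulation}
#' @export
trueMask <- function(sim) {
  stopifnot(is(sim, "CaSimulation"))
  sim@trueMask
}
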