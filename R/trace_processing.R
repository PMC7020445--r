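#' Fit a second-order polynomial photobleaching trend
#'
#' Ordinary least squares fit of \code{trace ~ a + b t + c t^2} over the
#' recording, used to model the smooth intensity loss from photobleaching.
#'
#' @param trace numeric vector of raw intensities.
#' @param times frame times in seconds (defaults to 0, dt, 2 dt, ... with
#'   dt = 10 s when omitted).
#' @return named numeric c(a, b, c).
#' @export
#' @examples
#' t <- seq(0, 590, by = 10)
#' fitBleachTrend(100 - 0.1 * t + 1e-4 * t^2, t)
fitBleachTrend <- function(trace, times = NULL) {
  if (length(trace) < 3L)
    stop("fitBleachTrend: at least 3 frames are needed to fit a quadratic")
  if (is.null(times)) times <- (seq_along(trace) - 1) * 10
  X <- cbind(1, times, times^2)
  cf <- stats::lm.fit(X, trace)$coefficients
  if (any(!is.finite(cf))) stop("fitBleachTrend: singular fit")
  stats::setNames(as.numeric(cf), c("a", "b", "c"))
}

#' Correct photobleaching by divisive quadratic detrending
#'
#' Fits the quadratic trend and divides it out, anchored at the first frame:
#' \code{corrected(t) = trace(t) trend(0) / trend(t)}. Division (rather than
#' subtraction) reflects the multiplicative nature of fluorophore loss and
#' preserves deltaF/F0 scale invariance. If the fitted trend is not strictly
#' positive over the recording the function falls back to subtractive
#' correction (\code{trace - trend + trend(0)}) with a warning.
#'
#' @inheritParams fitBleachTrend
#' @param coefs optional precomputed trend coefficients c(a, b, c).
#' @return list with elements \code{corrected} (numeric vector) and
#'   \code{coefs}.
#' @export
correctBleach <- function(trace, times = NULL, coefs = NULL) {
  if (is.null(times)) times <- (seq_along(trace) - 1) * 10
  if (is.null(coefs)) coefs <- fitBleachTrend(trace, times)
  trend <- coefs[["a"]] + coefs[["b"]] * times + coefs[["c"]] * times^2
  if (any(trend <= 0)) {
    warning("correctBleach: fitted trend not positive everywhere; ",
            "falling back to subtractive correction")
    corrected <- trace - trend + trend[1L]
  } else {
    corrected <- trace * trend[1L] / trend
  }
  list(corrected = corrected, coefs = coefs)
}

#' Compute deltaF/F0 from a bleach-corrected trace
#'
#' F0 is taken as a low quantile (default the 20th percentile) of the
#' corrected trace -- a robust stand-in for the basal fluorescence level when
#' spikes occupy a minority of frames -- and deltaF/F0 = (F - F0) / F0.
#'
#' @param corrected bleach-corrected intensity trace.
#' @param baselineQuantile quantile defining F0 (default 0.2).
#' @param cellId optional id used in error messages.
#' @return list with elements \code{dff} and \code{f0}.
#' @export
#' @examples
#' computeDff(c(100, 100, 200, 100))$dff
computeDff <- function(corrected, baselineQuantile = 0.2, cellId = NULL) {
  f0 <- stats::quantile(corrected, baselineQuantile, names = FALSE, type = 7)
  if (!is.finite(f0) || f0 <= 0)
    stop("computeDff: degenerate baseline (F0 <= 0)",
         if (!is.null(cellId)) paste0(" for cell ", cellId) else "")
  list(dff = (corrected - f0) / f0, f0 = f0)
}

#' Bleach-correct and normalise a TraceSet to deltaF/F0
#'
#' Applies \code{\link{correctBleach}} and \code{\link{computeDff}} to every
#' cell. With \code{maskSpikes = TRUE} the quadratic trend is refitted after
#' excluding frames in which a first-pass deltaF/F0 exceeds \code{ampMin}
#' (plus the two following frames, covering the transient decay), removing
#' the small upward bias spikes impose on the trend.
#'
#' @param ts a \linkS4class{TraceSet}.
#' @param baselineQuantile quantile defining F0 (default 0.2).
#' @param maskSpikes refit the trend on spike-free frames (default FALSE).
#' @param ampMin deltaF/F0 threshold used for masking (default 0.2).
#' @return A \linkS4class{NormalizedTraceSet}.
#' @export
normalizeTraces <- function(ts, baselineQuantile = 0.2, maskSpikes = FALSE,
                            ampMin = 0.2) {
  stopifnot(is(ts, "TraceSet"))
  raw <- rawTraces(ts)
  times <- frameTimes(ts)
  n <- nrow(raw)
  dffM <- matrix(0, n, ncol(raw), dimnames = dimnames(raw))
  f0 <- numeric(n)
  cf <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    cb <- correctBleach(raw[i, ], times)
    if (maskSpikes) {
      d0 <- computeDff(cb$corrected, baselineQuantile, rownames(raw)[i])
      hot <- which(d0$dff > ampMin)
      drop <- unique(pmin(ncol(raw), c(hot, hot + 1L, hot + 2L)))
      if (length(drop) && (ncol(raw) - length(drop)) >= 3L) {
        cfm <- fitBleachTrend(raw[i, -drop], times[-drop])
        cb <- correctBleach(raw[i, ], times, coefs = cfm)
      }
    }
    d <- computeDff(cb$corrected, baselineQuantile, rownames(raw)[i])
    dffM[i, ] <- d$dff
    f0[i] <- d$f0
    cf[i, ] <- cb$coefs
  }
  se <- SummarizedExperiment(
    assays = list(raw = raw, dff = dffM),
    rowData = S4Vectors::DataFrame(cell_id = rownames(raw), f0 = f0,
                                   bleach_a = cf[, 1L], bleach_b = cf[, 2L],
                                   bleach_c = cf[, 3L],
                                   row.names = rownames(raw)),
    colData = colData(ts))
  metadata(se)$frameInterval <- frameInterval(ts)
  metadata(se)$condition <- conditionLabel(ts)
  metadata(se)$baselineQuantile <- baselineQuantile
  new("NormalizedTraceSet", se)
}

# local maxima of a series (strictly above the previous sample, at least the
# next one); endpoints are not peaks
.localMaxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2L:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

# topographic prominence of each peak: height above the higher of the two key
# saddles (minima on the paths toward higher ground on each side)
.peakProminence <- function(x, peaks) {
  vapply(peaks, function(p) {
    v <- x[p]
    left <- p; lmin <- v
    while (left > 1L) {
      left <- left - 1L
      if (x[left] > v) break
      if (x[left] < lmin) lmin <- x[left]
    }
    right <- p; rmin <- v
    n <- length(x)
    while (right < n) {
      right <- right + 1L
      if (x[right] > v) break
      if (x[right] < rmin) rmin <- x[right]
    }
    v - max(lmin, rmin)
  }, numeric(1))
}

#' Detect calcium spikes in deltaF/F0 series
#'
#' Spikes are local maxima with deltaF/F0 of at least \code{ampMin},
#' topographic prominence of at least \code{prominenceMin}, and at least
#' \code{minSeparation} frames between accepted peaks (the larger peak wins a
#' conflict). Thresholds are configuration; the values used are recorded as
#' attributes of the result. The defaults put the amplitude threshold about
#' four standard deviations above the baseline at a deltaF/F0 noise level of
#' 0.05 (a quantile baseline sits slightly below the noise mean, which
#' effectively lowers any absolute threshold); thresholds closer to three
#' sigma admit spurious noise peaks at a rate of several percent per cell
#' per recording.
#'
#' @param x a numeric deltaF/F0 series or a \linkS4class{NormalizedTraceSet}.
#' @param ampMin minimum peak deltaF/F0 (default 0.25).
#' @param prominenceMin minimum topographic prominence (default 0.2).
#' @param minSeparation minimum frames between accepted peaks (default 2).
#' @param frameInterval seconds per frame, used for spike times when \code{x}
#'   is a numeric vector (default 10).
#' @return data.frame with columns cell_id, frame (1-based), time_s,
#'   amplitude; one row per spike.
#' @export
#' @examples
#' s <- c(0, 0, 0.4, 1.0, 0.5, 0.2, 0, 0)
#' detectSpikes(s)
detectSpikes <- function(x, ampMin = 0.25, prominenceMin = 0.2,
                         minSeparation = 2L, frameInterval = 10) {
  if (is(x, "NormalizedTraceSet")) {
    D <- dff(x)
    out <- lapply(seq_len(nrow(D)), function(i) {
      s <- .detectSpikesVec(D[i, ], ampMin, prominenceMin, minSeparation)
      if (!length(s$frame)) return(NULL)
      data.frame(cell_id = rownames(D)[i], frame = s$frame,
                 time_s = (s$frame - 1) * frameInterval(x),
                 amplitude = s$amplitude)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(cell_id = character(0), frame = integer(0),
                        time_s = numeric(0), amplitude = numeric(0))
  } else {
    s <- .detectSpikesVec(as.numeric(x), ampMin, prominenceMin, minSeparation)
    out <- data.frame(cell_id = rep("cell_001", length(s$frame)),
                      frame = s$frame,
                      time_s = (s$frame - 1) * frameInterval,
                      amplitude = s$amplitude)
  }
  attr(out, "params") <- list(ampMin = ampMin, prominenceMin = prominenceMin,
                              minSeparation = minSeparation)
  out
}

.detectSpikesVec <- function(dffv, ampMin, prominenceMin, minSeparation) {
  if (any(!is.finite(dffv))) stop("detectSpikes: series must be finite")
  peaks <- .localMaxima(dffv)
  if (length(peaks)) {
    prom <- .peakProminence(dffv, peaks)
    ok <- dffv[peaks] >= ampMin & prom >= prominenceMin
    peaks <- peaks[ok]
  }
  if (length(peaks) > 1L) {
    ord <- peaks[order(dffv[peaks], decreasing = TRUE)]
    accepted <- integer(0)
    for (p in ord) {
      if (!length(accepted) || min(abs(accepted - p)) >= minSeparation)
        accepted <- c(accepted, p)
    }
    peaks <- sort(accepted)
  }
  list(frame = as.integer(peaks), amplitude = dffv[peaks])
}

#' Compute the clustering features (spike count, Ca2+max)
#'
#' Spike count is the number of detected spikes per recording; Ca2+max is the
#' maximum deltaF/F0 over the whole trace (not only at spikes).
#'
#' @param nts a \linkS4class{NormalizedTraceSet}.
#' @param spikes spike table from \code{\link{detectSpikes}} (recomputed with
#'   default thresholds when omitted).
#' @param ... passed to \code{\link{detectSpikes}} when spikes are recomputed.
#' @return data.frame with columns cell_id, spike_count, ca_max, condition.
#' @export
computeFeatures <- function(nts, spikes = NULL, ...) {
  stopifnot(is(nts, "NormalizedTraceSet"))
  if (is.null(spikes)) spikes <- detectSpikes(nts, ...)
  D <- dff(nts)
  ids <- rownames(D)
  counts <- table(factor(spikes$cell_id, levels = ids))
  data.frame(cell_id = ids,
             spike_count = as.integer(counts[ids]),
             ca_max = pmax(apply(D, 1L, max), 0),
             condition = conditionLabel(nts),
             row.names = NULL)
}

#' Build a raster structure from spike tables
#'
#' One mark per spike, preserving the input cell order; times in seconds.
#'
#' @param spikes spike table from \code{\link{detectSpikes}}.
#' @param cellIds cell ordering of the raster rows (defaults to the order of
#'   first appearance in \code{spikes}).
#' @param frameInterval seconds per frame (default 10), used only when the
#'   spike table lacks a time_s column.
#' @return data.frame with columns cell_index, cell_id, frame, time_s.
#' @export
buildRaster <- function(spikes, cellIds = NULL, frameInterval = 10) {
  if (is.null(cellIds)) cellIds <- unique(spikes$cell_id)
  idx <- match(spikes$cell_id, cellIds)
  keep <- !is.na(idx)
  time_s <- if ("time_s" %in% names(spikes)) spikes$time_s[keep] else
    (spikes$frame[keep] - 1) * frameInterval
  out <- data.frame(cell_index = idx[keep],
                    cell_id = spikes$cell_id[keep],
                    frame = spikes$frame[keep],
                    time_s = time_s)
  attr(out, "nCells") <- length(cellIds)
  attr(out, "cellIds") <- cellIds
  out[order(out$cell_index, out$frame), , drop = FALSE]
}
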