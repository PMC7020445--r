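#' Segment active cells from a movie by principal-component analysis
#'
#' Pixel time series are centered over time and the leading principal
#' components of the (frames x pixels) matrix are computed from the frame-by-
#' frame covariance. An activity image is formed as the pixelwise
#' root-sum-of-squares of the top-component loadings (equivalently, the
#' temporal standard deviation captured by the retained components), so that
#' pixels whose intensity fluctuates coherently -- spiking cells -- light up
#' while background noise, which spreads over all components, stays dim. The
#' activity image is thresholded (Otsu by default), connected components are
#' extracted with 8-connectivity, size-filtered to [minArea, maxArea] pixels,
#' and relabelled 1..n.
#'
#' The number of retained components is the smaller of \code{nComponents} and
#' the number needed to explain \code{varExplained} of the total temporal
#' variance. An all-constant movie yields an empty mask, not an error.
#'
#' Because active cells occupy a small minority of pixels, the activity
#' histogram is dominated by the background mode; the default threshold is
#' therefore the robust background estimate median + madK * MAD, which keeps
#' dim (low-activity) cells above threshold. Otsu's method (applied to the
#' log-activity image to de-weight the bright tail) and a plain quantile cut
#' are available alternatives.
#'
#' @param movie a \linkS4class{CaMovie}.
#' @param nComponents maximum number of principal components (default 10).
#' @param varExplained variance fraction cap on retained components
#'   (default 0.99).
#' @param thresholdMethod "mad" (default), "otsu" or "quantile".
#' @param madK MAD multiplier for the "mad" threshold (default 6).
#' @param thresholdQuantile activity quantile when thresholdMethod =
#'   "quantile" (default 0.95).
#' @param minArea,maxArea admissible component sizes in pixels
#'   (defaults 20 and 2000).
#' @return A \linkS4class{LabelMask}.
#' @export
#' @examples
#' sim <- simulateMovie(simulatePopulation(simConfig(nCells = 3, noiseSd = 0),
#'                                         seed = 1),
#'                      height = 64, width = 64, seed = 2)
#' mask <- segmentMoviePCA(simMovie(sim))
#' nLabels(mask)
segmentMoviePCA <- function(movie, nComponents = 10, varExplained = 0.99,
                            thresholdMethod = c("mad", "otsu", "quantile"),
                            madK = 6, thresholdQuantile = 0.95,
                            minArea = 20, maxArea = 2000) {
  stopifnot(is(movie, "CaMovie"))
  thresholdMethod <- match.arg(thresholdMethod)
  d <- dim(movie@data)
  nf <- d[1L]; h <- d[2L]; w <- d[3L]
  if (nComponents < 1 || nComponents > nf)
    stop("segmentMoviePCA: nComponents must be in 1..nFrames")
  X <- matrix(movie@data, nf, h * w)      # frames x pixels, column-major pixels
  Xc <- sweep(X, 2L, colMeans(X))
  C <- tcrossprod(Xc)                     # frames x frames
  ev <- eigen(C, symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  total <- sum(lambda)
  if (total <= .Machine$double.eps * nf * h * w) {
    return(LabelMask(matrix(0L, h, w)))   # constant movie: nothing to segment
  }
  kVar <- which(cumsum(lambda) / total >= varExplained)[1L]
  k <- max(1L, min(as.integer(nComponents), kVar, nf - 1L))
  scores <- crossprod(Xc, ev$vectors[, seq_len(k), drop = FALSE])  # pixels x k
  activity <- sqrt(rowSums(scores^2) / (nf - 1))
  activityImg <- matrix(activity, h, w)
  .maskFromActivity(activityImg, thresholdMethod, madK, thresholdQuantile,
                    minArea, maxArea)
}

#' Segment active cells by plain temporal variance
#'
#' Fallback segmentation behind the same interface as
#' \code{\link{segmentMoviePCA}}: the activity image is simply the per-pixel
#' temporal standard deviation.
#'
#' @inheritParams segmentMoviePCA
#' @return A \linkS4class{LabelMask}.
#' @export
segmentMovieVariance <- function(movie,
                                 thresholdMethod = c("mad", "otsu", "quantile"),
                                 madK = 6, thresholdQuantile = 0.95,
                                 minArea = 20, maxArea = 2000) {
  stopifnot(is(movie, "CaMovie"))
  thresholdMethod <- match.arg(thresholdMethod)
  d <- dim(movie@data)
  nf <- d[1L]; h <- d[2L]; w <- d[3L]
  X <- matrix(movie@data, nf, h * w)
  v <- colMeans(X^2) - colMeans(X)^2
  if (max(v) <= .Machine$double.eps * max(1, max(X))^2)
    return(LabelMask(matrix(0L, h, w)))
  activityImg <- matrix(sqrt(pmax(v, 0) * nf / (nf - 1)), h, w)
  .maskFromActivity(activityImg, thresholdMethod, madK, thresholdQuantile,
                    minArea, maxArea)
}

.maskFromActivity <- function(activityImg, thresholdMethod, madK,
                              thresholdQuantile, minArea, maxArea) {
  a <- as.vector(activityImg)
  fg <- switch(thresholdMethod,
    mad = activityImg > stats::median(a) + madK * stats::mad(a),
    otsu = {
      la <- log(pmax(a, .Machine$double.xmin))
      activityImg > exp(.otsuThreshold(la))
    },
    quantile = activityImg >
      stats::quantile(a, thresholdQuantile, names = FALSE))
  lab <- .labelComponents8(fg)
  .sizeFilterRelabel(lab, minArea, maxArea)
}

# Otsu's threshold on a numeric vector (maximises between-class variance over
# a 256-bin histogram)
.otsuThreshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  denom <- omega * (1 - omega)
  sigmaB <- ifelse(denom > 0, (muT * omega - mu)^2 / denom, 0)
  mids[which.max(sigmaB)]
}

# 8-connected component labelling by iterative minimum-label propagation
.labelComponents8 <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(Inf, h, w)
  idx <- which(fg)
  if (!length(idx)) return(matrix(0L, h, w))
  lab[idx] <- seq_along(idx)
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    nb <- lab
    for (o in offs) nb <- pmin(nb, shift(lab, o[1L], o[2L]))
    nb[!fg] <- Inf
    if (all(nb[idx] == lab[idx])) break
    lab <- nb
  }
  out <- matrix(0L, h, w)
  out[idx] <- as.integer(match(lab[idx], sort(unique(lab[idx]))))
  out
}

.sizeFilterRelabel <- function(lab, minArea, maxArea) {
  n <- max(lab)
  if (n == 0L) return(LabelMask(lab))
  areas <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(areas >= minArea & areas <= maxArea)
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  sel <- lab > 0
  out[sel] <- remap[lab[sel]]
  LabelMask(out)
}

#' Extract per-cell mean-intensity traces from a movie
#'
#' The trace of cell i at frame t is the mean movie intensity over the pixels
#' labelled i; rows are ordered by ascending label.
#'
#' @param movie a \linkS4class{CaMovie}.
#' @param mask a \linkS4class{LabelMask} with matching spatial dimensions.
#' @param condition optional condition label for the returned traces.
#' @return A \linkS4class{TraceSet} (empty if the mask has no labels).
#' @export
extractTraces <- function(movie, mask, condition = NA_character_) {
  stopifnot(is(movie, "CaMovie"), is(mask, "LabelMask"))
  d <- dim(movie@data)
  L <- labelMatrix(mask)
  if (nrow(L) != d[2L] || ncol(L) != d[3L])
    stop("extractTraces: mask dimensions do not match the movie")
  n <- nLabels(mask)
  nf <- d[1L]
  if (n == 0L) {
    return(TraceSet(matrix(numeric(0), 0L, nf),
                    frameInterval = movie@frameInterval,
                    cellIds = character(0), condition = condition))
  }
  labs <- as.vector(L)
  sel <- labs > 0
  X <- matrix(movie@data, nf, d[2L] * d[3L])      # frames x pixels
  sums <- rowsum(t(X[, sel, drop = FALSE]), group = labs[sel])  # labels x frames
  counts <- tabulate(labs[sel], nbins = n)
  traces <- sums / counts
  TraceSet(traces, frameInterval = movie@frameInterval,
           cellIds = sprintf("cell_%03d", seq_len(n)), condition = condition)
}

#' Match predicted ROIs to ground-truth ROIs by IoU
#'
#' Greedy one-to-one matching by descending intersection-over-union; pairs
#' below \code{iouMin} remain unmatched.
#'
#' @param predictedMask,trueMask \linkS4class{LabelMask}s of equal dimensions.
#' @param iouMin minimum IoU for a match (default 0.5).
#' @return data.frame with columns true_id, pred_id (NA when unmatched), iou.
#' @export
matchRois <- function(predictedMask, trueMask, iouMin = 0.5) {
  P <- labelMatrix(predictedMask)
  T_ <- labelMatrix(trueMask)
  if (!all(dim(P) == dim(T_)))
    stop("matchRois: masks must have identical dimensions")
  nT <- nLabels(trueMask); nP <- nLabels(predictedMask)
  res <- data.frame(true_id = seq_len(nT), pred_id = NA_integer_,
                    iou = NA_real_)
  if (nT == 0L || nP == 0L) return(res)
  areaT <- tabulate(T_[T_ > 0], nbins = nT)
  areaP <- tabulate(P[P > 0], nbins = nP)
  both <- T_ > 0 & P > 0
  if (!any(both)) return(res)
  inter <- table(true = T_[both], pred = P[both])
  pairs <- as.data.frame(inter, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$Freq > 0, ]
  ti <- as.integer(pairs$true); pi <- as.integer(pairs$pred)
  iou <- pairs$Freq / (areaT[ti] + areaP[pi] - pairs$Freq)
  ord <- order(iou, decreasing = TRUE)
  usedT <- logical(nT); usedP <- logical(nP)
  for (j in ord) {
    t_ <- ti[j]; p_ <- pi[j]
    if (iou[j] < iouMin) break
    if (usedT[t_] || usedP[p_]) next
    usedT[t_] <- TRUE; usedP[p_] <- TRUE
    res$pred_id[t_] <- p_
    res$iou[t_] <- iou[j]
  }
  res
}
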