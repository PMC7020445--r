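#' Simulation configuration for synthetic calcium-imaging populations
#'
#' Defines a mixed population of four activity classes (hyperactive, moderate,
#' low, silent) recorded at a fixed frame interval. Calcium events are placed
#' at random frames, rise within one frame and decay exponentially;
#' photobleaching enters as a multiplicative quadratic-in-time trend; Gaussian
#' noise is added in intensity units. Class composition is exact: the
#' configured proportions are converted to integer per-class cell counts
#' (largest-remainder rounding), so two populations simulated from the same
#' configuration share the same true composition.
#'
#' Per-class spike counts are Poisson with the configured rate. When
#' \code{enforceCountRange} is TRUE (default) counts are rejection-sampled
#' into the class's admissible range (\code{countRange}), so that the
#' generating classes respect the activity-class boundaries (> 6 spikes for
#' hyperactive, 1-6 for moderate and low, 0 for silent) and are recoverable
#' by boundary classification. Set it to FALSE for plain Poisson counts.
#'
#' @param nCells number of cells (default 160, one recording's population).
#' @param frameInterval seconds between frames (default 10).
#' @param nFrames number of frames (default 60, i.e. a 600 s recording).
#' @param classProportions named fractions per activity class, summing to 1.
#' @param spikeRate named Poisson mean events per recording per class.
#' @param ampMean,ampSd named mean/sd of event amplitude (deltaF/F0) per class.
#' @param countRange named list of c(min, max) admissible spike counts.
#' @param enforceCountRange logical, rejection-sample counts into countRange.
#' @param decayTau event decay time constant, seconds (default 15).
#' @param riseFrames frames over which an event rises (default 1, i.e.
#'   full amplitude at the spike frame).
#' @param f0Baseline baseline fluorescence intensity (default 100).
#' @param bleachCoefs numeric c(b, c): multiplicative trend 1 + b t + c t^2
#'   (default c(-4e-4, 1e-7), about 20 percent decay over 600 s).
#' @param noiseSd additive Gaussian noise sd, intensity units (default 2).
#' @param seed optional integer seed stored with the config.
#' @return A validated list of class \code{simConfig}.
#' @export
#' @examples
#' cfg <- simConfig(nCells = 10, noiseSd = 0)
#' sim <- simulatePopulation(cfg, seed = 1)
#' sim
simConfig <- function(nCells = 160,
                      frameInterval = 10,
                      nFrames = 60,
                      classProportions = c(hyperactive = 0.10, moderate = 0.30,
                                           low = 0.40, silent = 0.20),
                      spikeRate = c(hyperactive = 10, moderate = 3.5,
                                    low = 2.5, silent = 0),
                      ampMean = c(hyperactive = 0.9, moderate = 0.7,
                                  low = 0.35, silent = 0),
                      ampSd = c(hyperactive = 0.15, moderate = 0.10,
                                low = 0.04, silent = 0),
                      countRange = list(hyperactive = c(7, Inf),
                                        moderate = c(1, 6),
                                        low = c(1, 6),
                                        silent = c(0, 0)),
                      enforceCountRange = TRUE,
                      decayTau = 15,
                      riseFrames = 1,
                      f0Baseline = 100,
                      bleachCoefs = c(b = -4e-4, c = 1e-7),
                      noiseSd = 2,
                      seed = NULL) {
  cls <- activityClasses()
  cfg <- list(nCells = as.integer(nCells), frameInterval = frameInterval,
              nFrames = as.integer(nFrames),
              classProportions = .namedPerClass(classProportions, cls),
              spikeRate = .namedPerClass(spikeRate, cls),
              ampMean = .namedPerClass(ampMean, cls),
              ampSd = .namedPerClass(ampSd, cls),
              countRange = countRange[cls],
              enforceCountRange = isTRUE(enforceCountRange),
              decayTau = decayTau, riseFrames = as.integer(riseFrames),
              f0Baseline = f0Baseline,
              bleachCoefs = setNames(as.numeric(bleachCoefs), c("b", "c")),
              noiseSd = noiseSd, seed = seed)
  .validateSimConfig(cfg)
  class(cfg) <- c("simConfig", "list")
  cfg
}

.namedPerClass <- function(x, cls) {
  if (is.null(names(x))) names(x) <- cls[seq_along(x)]
  x <- x[cls]
  names(x) <- cls
  x
}

.validateSimConfig <- function(cfg) {
  num <- c(cfg$classProportions, cfg$spikeRate, cfg$ampMean, cfg$ampSd,
           cfg$frameInterval, cfg$decayTau, cfg$f0Baseline, cfg$bleachCoefs,
           cfg$noiseSd)
  if (!all(is.finite(num)))
    stop("simConfig: all numeric configuration values must be finite")
  if (abs(sum(cfg$classProportions) - 1) > 1e-9)
    stop("simConfig: classProportions must sum to 1")
  if (any(cfg$classProportions < 0) || any(cfg$spikeRate < 0) ||
      any(cfg$ampSd < 0) || cfg$noiseSd < 0)
    stop("simConfig: proportions, rates and sds must be non-negative")
  if (cfg$nFrames < 2L) stop("simConfig: nFrames must be >= 2")
  if (cfg$frameInterval <= 0 || cfg$decayTau <= 0 || cfg$f0Baseline <= 0)
    stop("simConfig: frameInterval, decayTau and f0Baseline must be positive")
  if (cfg$enforceCountRange) {
    for (cl in activityClasses()) {
      r <- cfg$countRange[[cl]]
      if (cfg$classProportions[[cl]] > 0 && r[1] > 0 &&
          cfg$spikeRate[[cl]] <= 0)
        stop("simConfig: class '", cl, "' requires >= ", r[1],
             " spikes but has zero spike rate")
    }
  }
  invisible(cfg)
}

#' Condition presets for the synthetic generator
#'
#' "control" reproduces an unstressed mixed-culture composition
#' (10/30/40/20 percent hyperactive/moderate/low/silent); "hypoxia" raises the
#' hyperactive and moderate fractions and lowers the low/silent fractions
#' (25/40/25/10) and raises the hyperactive event amplitude from 0.9 to 1.2.
#' The presets reproduce the direction of the subpopulation shifts observed
#' under CoCl2-mimicked hypoxia; the exact percentages are generator
#' configuration, not estimates.
#'
#' @param condition "control" or "hypoxia".
#' @param ... overrides passed on to \code{\link{simConfig}}.
#' @return A \code{simConfig}.
#' @export
#' @examples
#' conditionPreset("hypoxia")$classProportions
conditionPreset <- function(condition = c("control", "hypoxia"), ...) {
  condition <- match.arg(condition)
  args <- list(...)
  if (condition == "hypoxia") {
    if (is.null(args$classProportions))
      args$classProportions <- c(hyperactive = 0.25, moderate = 0.40,
                                 low = 0.25, silent = 0.10)
    if (is.null(args$ampMean))
      args$ampMean <- c(hyperactive = 1.2, moderate = 0.7, low = 0.35,
                        silent = 0)
  }
  do.call(simConfig, args)
}

# largest-remainder apportionment of n cells to the class proportions
.classCounts <- function(proportions, n) {
  raw <- proportions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

# Poisson count, optionally rejection-sampled into [lo, hi]
.drawCount <- function(rate, range, enforce, maxFrames) {
  hi <- min(range[2], maxFrames)
  lo <- range[1]
  if (!enforce) return(min(stats::rpois(1L, rate), maxFrames))
  if (rate == 0 && lo <= 0) return(0L)
  for (i in seq_len(10000L)) {
    k <- stats::rpois(1L, rate)
    if (k >= lo && k <= hi) return(as.integer(k))
  }
  as.integer(max(lo, min(hi, round(rate))))
}

# spike frames: uniform without replacement over the admissible window with a
# minimum separation of 2 frames (events resolvable at the sampling rate)
.drawSpikeFrames <- function(k, nFrames, minSep = 2L) {
  if (k == 0L) return(integer(0))
  candidates <- seq(3L, nFrames - 1L)     # 1-based; avoids first/last frames
  for (try in seq_len(200L)) {
    f <- sort(sample(candidates, k))
    if (k == 1L || min(diff(f)) >= minSep) return(f)
  }
  # greedy fallback: accept shuffled candidates respecting the separation
  f <- integer(0)
  for (cand in sample(candidates)) {
    if (!length(f) || min(abs(f - cand)) >= minSep) f <- c(f, cand)
    if (length(f) == k) break
  }
  sort(f)
}

# deltaF/F0 time course from events: linear rise over riseFrames, exponential
# decay with time constant decayTau
.eventKernelTrace <- function(frames, amps, nFrames, frameInterval, decayTau,
                              riseFrames = 1L) {
  dffv <- numeric(nFrames)
  tt <- seq_len(nFrames)
  for (j in seq_along(frames)) {
    f <- frames[j]; A <- amps[j]
    after <- tt >= f
    dffv[after] <- dffv[after] + A * exp(-(tt[after] - f) * frameInterval / decayTau)
    if (riseFrames > 1L) {
      for (r in seq_len(riseFrames - 1L)) {
        i <- f - r
        if (i >= 1L) dffv[i] <- dffv[i] + A * (riseFrames - r) / riseFrames
      }
    }
  }
  dffv
}

#' Simulate a ground-truthed population of calcium traces
#'
#' Draws each cell from its activity class (exact class composition, Poisson
#' spike counts, Gaussian event amplitudes), builds the deltaF/F0 time course
#' from the event kernel, and converts it to raw fluorescence with baseline,
#' multiplicative quadratic photobleaching and additive Gaussian noise:
#' \code{raw(t) = f0 (1 + dff(t)) (1 + b t + c t^2) + noise}. Raw intensities
#' are clipped at zero. Fully reproducible for a given (config, seed).
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed integer seed; defaults to \code{config$seed}.
#' @param condition condition label stored with the traces.
#' @return A \linkS4class{CaSimulation} (traces + ground truth, no movie).
#' @export
#' @examples
#' sim <- simulatePopulation(simConfig(nCells = 20), seed = 7)
#' groundTruth(sim)[1:3, c("cell_id", "true_class")]
simulatePopulation <- function(config, seed = config$seed,
                               condition = "control") {
  .validateSimConfig(config)
  if (is.null(seed)) stop("simulatePopulation: a seed is required")
  withr::with_seed(as.integer(seed), {
    cls <- activityClasses()
    counts <- .classCounts(config$classProportions, config$nCells)
    classes <- rep(cls, counts)
    n <- config$nCells
    nf <- config$nFrames
    tt <- (seq_len(nf) - 1) * config$frameInterval
    bleach <- 1 + config$bleachCoefs[["b"]] * tt + config$bleachCoefs[["c"]] * tt^2
    maxSpikes <- length(seq(3L, nf - 1L)) %/% 2L + 1L

    raw <- matrix(0, n, nf)
    spikeFrames <- vector("list", n)
    amplitudes <- vector("list", n)
    for (i in seq_len(n)) {
      cl <- classes[i]
      k <- .drawCount(config$spikeRate[[cl]], config$countRange[[cl]],
                      config$enforceCountRange, maxSpikes)
      f <- .drawSpikeFrames(k, nf)
      A <- if (length(f)) pmax(stats::rnorm(length(f), config$ampMean[[cl]],
                                            config$ampSd[[cl]]), 0.01)
           else numeric(0)
      dffv <- .eventKernelTrace(f, A, nf, config$frameInterval,
                                config$decayTau, config$riseFrames)
      tr <- config$f0Baseline * (1 + dffv) * bleach
      if (config$noiseSd > 0) tr <- tr + stats::rnorm(nf, 0, config$noiseSd)
      raw[i, ] <- pmax(tr, 0)
      spikeFrames[[i]] <- f
      amplitudes[[i]] <- A
    }
    ids <- sprintf("cell_%03d", seq_len(n))
    gt <- S4Vectors::DataFrame(
      cell_id = ids,
      true_class = classes,
      spike_frames = IRanges::IntegerList(spikeFrames),
      amplitudes = IRanges::NumericList(amplitudes),
      true_spike_count = lengths(spikeFrames),
      row.names = ids)
    traces <- TraceSet(raw, frameInterval = config$frameInterval,
                       cellIds = ids, condition = condition)
    new("CaSimulation", config = unclass(config), groundTruth = gt,
        traces = traces, movie = NULL, trueMask = NULL,
        conditionLabel = condition)
  })
}

#' Simulate a movie from a simulated population
#'
#' Places disc-shaped, non-overlapping cell footprints at random positions and
#' paints each footprint pixel with the cell's raw trace (plus optional
#' per-pixel noise); pixels outside any footprint hold a constant background
#' level (plus noise). Returns the movie together with the ground-truth label
#' mask.
#'
#' @param sim a \linkS4class{CaSimulation} from \code{\link{simulatePopulation}}.
#' @param height,width movie dimensions in pixels (default 256 x 256).
#' @param cellRadius footprint radius in pixels (default 5).
#' @param backgroundLevel background intensity (default half the baseline).
#' @param noiseSd per-pixel Gaussian noise sd (default 0).
#' @param seed integer seed.
#' @param maxTries placement attempts per cell before giving up.
#' @return The input \linkS4class{CaSimulation} with its \code{movie} and
#'   \code{trueMask} slots filled.
#' @export
simulateMovie <- function(sim, height = 256L, width = 256L, cellRadius = 5,
                          backgroundLevel = NULL, noiseSd = 0,
                          seed = 1L, maxTries = 5000L) {
  stopifnot(is(sim, "CaSimulation"))
  traces <- rawTraces(simTraces(sim))
  n <- nrow(traces)
  nf <- ncol(traces)
  if (is.null(backgroundLevel))
    backgroundLevel <- sim@config$f0Baseline * 0.5
  withr::with_seed(as.integer(seed), {
    margin <- ceiling(cellRadius) + 1L
    minDist <- 2 * cellRadius + 1     # strictly disjoint footprints
    centers <- matrix(NA_real_, n, 2L)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        r <- stats::runif(1, margin, height - margin)
        cc <- stats::runif(1, margin, width - margin)
        if (i == 1L || all(sqrt((centers[seq_len(i - 1L), 1L] - r)^2 +
                                (centers[seq_len(i - 1L), 2L] - cc)^2) >= minDist)) {
          centers[i, ] <- c(r, cc); placed <- TRUE; break
        }
      }
      if (!placed)
        stop("simulateMovie: could not place ", n, " non-overlapping cells ",
             "of radius ", cellRadius, " in a ", height, "x", width, " image")
    }
    labels <- matrix(0L, height, width)
    rowIdx <- matrix(seq_len(height), height, width)
    colIdx <- matrix(rep(seq_len(width), each = height), height, width)
    footprints <- vector("list", n)
    for (i in seq_len(n)) {
      inside <- (rowIdx - centers[i, 1L])^2 + (colIdx - centers[i, 2L])^2 <=
        cellRadius^2
      labels[inside] <- i
      footprints[[i]] <- which(inside)
    }
    movie <- array(backgroundLevel, dim = c(nf, height, width))
    if (noiseSd > 0)
      movie <- movie + array(stats::rnorm(length(movie), 0, noiseSd), dim(movie))
    for (i in seq_len(n)) {
      px <- footprints[[i]]
      for (f in seq_len(nf)) {
        vals <- traces[i, f]
        if (noiseSd > 0) vals <- vals + stats::rnorm(length(px), 0, noiseSd)
        movie[f + (px - 1L) * nf] <- vals   # flat index: element (f, row, col)
      }
    }
    movie <- pmax(movie, 0)
    sim@movie <- CaMovie(movie, frameInterval = frameInterval(simTraces(sim)))
    sim@trueMask <- LabelMask(labels)
    sim@groundTruth$footprint <- IRanges::IntegerList(footprints)
    sim
  })
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' The reference gene has a constant Ct in every condition; for each target
#' gene the treated-condition Ct equals the control Ct minus log2 of the true
#' fold change. Gaussian cycle noise (sd \code{ctNoiseSd}) is added to target
#' Ct values of both conditions; the reference gene is noise-free.
#'
#' @param trueFoldPerGene named numeric vector of true fold changes (> 0).
#' @param nReplicates replicates per gene and condition (default 3).
#' @param ctNoiseSd Gaussian sd of target Ct values, cycles (default 0).
#' @param seed integer seed.
#' @param referenceGene reference (housekeeping) gene name (default "ACTB").
#' @param conditions character(2): control and treated condition names.
#' @param baseCt control-condition Ct of every target gene (default 26).
#' @param referenceCt Ct of the reference gene (default 18).
#' @return data.frame with columns gene, condition, replicate, ct, plus the
#'   reference gene name as attribute \code{"referenceGene"}.
#' @export
simulateQpcr <- function(trueFoldPerGene, nReplicates = 3, ctNoiseSd = 0,
                         seed = 1L, referenceGene = "ACTB",
                         conditions = c("no_stress", "hypoxia"),
                         baseCt = 26, referenceCt = 18) {
  if (any(trueFoldPerGene <= 0)) stop("simulateQpcr: fold changes must be > 0")
  if (nReplicates < 1) stop("simulateQpcr: nReplicates must be >= 1")
  genes <- names(trueFoldPerGene)
  if (is.null(genes)) stop("simulateQpcr: trueFoldPerGene must be named")
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (cond in conditions) {
      for (rep_i in seq_len(nReplicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = referenceGene, condition = cond, replicate = rep_i,
          ct = referenceCt)
        for (g in genes) {
          ct <- if (cond == conditions[2L])
            baseCt - log2(trueFoldPerGene[[g]]) else baseCt
          if (ctNoiseSd > 0) ct <- ct + stats::rnorm(1, 0, ctNoiseSd)
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, condition = cond, replicate = rep_i, ct = ct)
        }
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "referenceGene") <- referenceGene
    out
  })
}

#' Simulate an Alamar-blue viability plate with known viability
#'
#' Treated-well absorbance is constructed as
#' \code{blank + (percent/100) (control - blank) + noise}, so that the
#' blank-subtracted percentage-of-control computation recovers the configured
#' viability exactly in the noise-free case.
#'
#' @param truePercentPerDose named numeric vector, true viability percent per
#'   dose (names are doses in uM).
#' @param blankAbs blank absorbance (default 0.1).
#' @param controlAbs untreated-control absorbance (default 1.1; must exceed
#'   the blank).
#' @param noiseSd Gaussian absorbance noise sd (default 0).
#' @param nReplicates wells per dose and for blank/control (default 3).
#' @param seed integer seed.
#' @return data.frame with columns well, dose_um, absorbance, role
#'   (blank/control/treated).
#' @export
simulateViability <- function(truePercentPerDose, blankAbs = 0.1,
                              controlAbs = 1.1, noiseSd = 0, nReplicates = 3,
                              seed = 1L) {
  if (controlAbs <= blankAbs)
    stop("simulateViability: control absorbance must exceed the blank")
  if (any(truePercentPerDose < 0) || any(truePercentPerDose > 120))
    stop("simulateViability: viability percent must be in [0, 120]")
  doses <- names(truePercentPerDose)
  if (is.null(doses)) stop("simulateViability: truePercentPerDose must be named")
  withr::with_seed(as.integer(seed), {
    mk <- function(role, dose, value, k) data.frame(
      well = sprintf("%s_%s_%d", role, dose, seq_len(k)),
      dose_um = as.numeric(dose), absorbance = value, role = role)
    noise <- function(k) if (noiseSd > 0) stats::rnorm(k, 0, noiseSd) else 0
    out <- rbind(
      mk("blank", 0, blankAbs + noise(nReplicates), nReplicates),
      mk("control", 0, controlAbs + noise(nReplicates), nReplicates))
    for (d in doses) {
      ab <- blankAbs + truePercentPerDose[[d]] / 100 * (controlAbs - blankAbs) +
        noise(nReplicates)
      out <- rbind(out, mk("treated", d, ab, nReplicates))
    }
    rownames(out) <- NULL
    out
  })
}
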