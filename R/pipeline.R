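#' @importFrom rlang .data
NULL

#' Build a pipeline configuration
#'
#' Assembles and validates the configuration of an end-to-end run. Each
#' condition is given either a trace CSV path, a movie TIFF path, or a
#' simulation preset name ("control"/"hypoxia"). Defaults mirror the study
#' constants: 10 s frame interval over 600 s, k = 4 clusters fitted on the
#' control condition, boundary defaults of 6 spikes and 0.5 deltaF/F0,
#' subsampling 90 cells (60 percent of a 160-cell population) five times,
#' significance level 0.05.
#'
#' @param conditions named list; each element a list with one of
#'   \code{traces} (CSV path), \code{movie} (TIFF path) or \code{preset}
#'   (simulation preset name), and optionally \code{nCells}.
#' @param control name of the control condition (boundaries are derived from
#'   it; default first condition).
#' @param outDir output directory.
#' @param seed integer master seed.
#' @param frameInterval seconds per frame (default 10).
#' @param baselineQuantile F0 quantile (default 0.2).
#' @param ampMin,prominenceMin,minSeparation spike-detector settings.
#' @param k clusters for the control fit (default 4).
#' @param nRestarts k-means restarts (default 50).
#' @param fraction,sampleSize,nRepeats subsampling scheme (defaults 0.6, 90,
#'   5).
#' @param alpha significance level (default 0.05).
#' @param segmentation list of segmentation settings (nComponents, minArea,
#'   maxArea).
#' @return validated config list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(conditions, control = names(conditions)[1L],
                           outDir = tempfile("calcipop_run_"), seed = 1L,
                           frameInterval = 10, baselineQuantile = 0.2,
                           ampMin = 0.2, prominenceMin = 0.15,
                           minSeparation = 2L, k = 4L, nRestarts = 50L,
                           fraction = 0.6, sampleSize = 90L, nRepeats = 5L,
                           alpha = 0.05,
                           segmentation = list(nComponents = 10,
                                               minArea = 20, maxArea = 2000)) {
  if (!length(conditions) || is.null(names(conditions)))
    stop("pipelineConfig: conditions must be a named list")
  if (!control %in% names(conditions))
    stop("pipelineConfig: control condition '", control, "' not defined")
  for (nm in names(conditions)) {
    cnd <- conditions[[nm]]
    if (!any(c("traces", "movie", "preset") %in% names(cnd)))
      stop("pipelineConfig: condition '", nm,
           "' needs a traces, movie or preset entry")
    for (p in intersect(c("traces", "movie"), names(cnd)))
      if (!file.exists(cnd[[p]]))
        stop("pipelineConfig: input '", cnd[[p]], "' of condition '", nm,
             "' does not exist")
  }
  cfg <- list(conditions = conditions, control = control, outDir = outDir,
              seed = as.integer(seed), frameInterval = frameInterval,
              baselineQuantile = baselineQuantile, ampMin = ampMin,
              prominenceMin = prominenceMin,
              minSeparation = as.integer(minSeparation), k = as.integer(k),
              nRestarts = as.integer(nRestarts), fraction = fraction,
              sampleSize = sampleSize, nRepeats = as.integer(nRepeats),
              alpha = alpha, segmentation = segmentation)
  class(cfg) <- c("pipelineConfig", "list")
  cfg
}

.logStage <- function(...) message("[calcipop] ", sprintf(...))

#' Run the full analysis pipeline
#'
#' Executes segmentation (for movie inputs) or trace loading or simulation,
#' bleach correction and deltaF/F0 normalisation, spike detection, feature
#' computation, k-means clustering of the control condition, cluster naming
#' and boundary derivation, boundary classification of every condition,
#' subsampled subpopulation profiling, Kruskal-Wallis condition comparisons
#' (when two or more conditions are present) and figure rendering. All
#' parameters actually used are logged; the run is deterministic given the
#' seed. A manifest registering every output file is written even when a
#' stage fails (with the failing stage recorded).
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return the manifest, invisibly (a list; also written as manifest.json).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("CalciPop")),
                   config = unclass(config), seeds = list(master = config$seed),
                   counts = list(), files = character(0), status = "running",
                   failed_stage = NULL)
  reg <- function(f) manifest$files <<- c(manifest$files, basename(f))
  finish <- function() {
    manifest$files <<- unique(c(manifest$files, "manifest.json"))
    mf <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
    invisible(manifest)
  }
  stage <- "setup"
  tryCatch({
    results <- list()
    condSeed <- config$seed
    for (nm in names(config$conditions)) {
      stage <- paste0("input:", nm)
      cnd <- config$conditions[[nm]]
      condSeed <- condSeed + 1L
      if (!is.null(cnd$movie)) {
        .logStage("condition %s: segmenting movie %s", nm, cnd$movie)
        movie <- readCaMovie(cnd$movie, config$frameInterval)
        mask <- segmentMoviePCA(movie,
                                nComponents = config$segmentation$nComponents,
                                minArea = config$segmentation$minArea,
                                maxArea = config$segmentation$maxArea)
        mf <- file.path(outDir, paste0("mask_", nm, ".tif"))
        writeLabelMask(mask, mf); reg(mf)
        reg(file.path(outDir, paste0("mask_", nm, "_rois.csv")))
        ts <- extractTraces(movie, mask, condition = nm)
      } else if (!is.null(cnd$traces)) {
        .logStage("condition %s: reading traces %s", nm, cnd$traces)
        ts <- readTraceCSV(cnd$traces, condition = nm)
      } else {
        .logStage("condition %s: simulating preset '%s' (seed %d)", nm,
                  cnd$preset, condSeed)
        scfg <- conditionPreset(cnd$preset,
                                nCells = cnd$nCells %||% 160,
                                frameInterval = config$frameInterval)
        sim <- simulatePopulation(scfg, seed = condSeed, condition = nm)
        manifest$seeds[[nm]] <- condSeed
        ts <- simTraces(sim)
        tf <- file.path(outDir, paste0("traces_", nm, ".csv"))
        writeTraceCSV(ts, tf); reg(tf)
        gf <- file.path(outDir, paste0("ground_truth_", nm, ".csv"))
        writeGroundTruthCSV(sim, gf); reg(gf)
      }
      stage <- paste0("process:", nm)
      .logStage("condition %s: %d cells; F0 quantile %.2f; detector amp >= %.2f, prominence >= %.2f, separation >= %d",
                nm, nrow(ts), config$baselineQuantile, config$ampMin,
                config$prominenceMin, config$minSeparation)
      nts <- normalizeTraces(ts, baselineQuantile = config$baselineQuantile)
      spikes <- detectSpikes(nts, ampMin = config$ampMin,
                             prominenceMin = config$prominenceMin,
                             minSeparation = config$minSeparation)
      features <- computeFeatures(nts, spikes)
      sf <- file.path(outDir, paste0("spikes_", nm, ".csv"))
      utils::write.csv(spikes, sf, row.names = FALSE); reg(sf)
      results[[nm]] <- list(nts = nts, spikes = spikes, features = features)
      manifest$counts[[nm]] <- list(cells = nrow(ts), spikes = nrow(spikes))
    }

    stage <- "cluster"
    ctrl <- config$control
    .logStage("clustering control ('%s') features: k = %d, %d restarts, seed %d",
              ctrl, config$k, config$nRestarts, config$seed)
    model <- clusterFeatures(results[[ctrl]]$features, k = config$k,
                             seed = config$seed,
                             nRestarts = config$nRestarts)
    mapping <- nameClusters(model)
    boundaries <- deriveBoundaries(model, mapping, results[[ctrl]]$features)
    bf <- file.path(outDir, "boundaries.json")
    writeBoundariesJSON(boundaries, bf); reg(bf)

    stage <- "classify"
    allFeatures <- list()
    for (nm in names(results)) {
      fts <- results[[nm]]$features
      fts$class <- classifyCells(fts, boundaries)
      fts$cluster <- if (nm == ctrl)
        unname(clusterAssignments(model)[fts$cell_id]) else NA_integer_
      results[[nm]]$features <- fts
      allFeatures[[nm]] <- fts
      ff <- file.path(outDir, paste0("features_", nm, ".csv"))
      utils::write.csv(fts, ff, row.names = FALSE); reg(ff)
    }

    stage <- "profiles"
    profiles <- do.call(rbind, lapply(seq_along(results), function(i) {
      nm <- names(results)[i]
      subsampleProfiles(results[[nm]]$features, boundaries,
                        fraction = config$fraction,
                        sampleSize = config$sampleSize,
                        nRepeats = config$nRepeats,
                        seed = config$seed + 1000L + i)
    }))
    pf <- file.path(outDir, "profiles.csv")
    utils::write.csv(profiles, pf, row.names = FALSE); reg(pf)
    manifest$counts$profiles <- nrow(profiles)

    if (length(results) >= 2L) {
      stage <- "condition-tests"
      tests <- compareConditions(profiles, alpha = config$alpha)
      tf <- file.path(outDir, "condition_tests.json")
      jsonlite::write_json(tests, tf, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows"); reg(tf)
    } else {
      .logStage("single condition: skipping condition tests")
    }

    stage <- "figures"
    flat <- list(
      nts = results[[ctrl]]$nts, spikes = results[[ctrl]]$spikes,
      features = do.call(rbind, allFeatures), profiles = profiles)
    for (f in renderFigures(flat, outDir)) reg(f)

    manifest$status <- "ok"
    .logStage("done: %d files in %s", length(manifest$files), outDir)
    finish()
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    finish()
    stop(e)
  })
}
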