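#' Read a multi-frame grayscale TIFF as a CaMovie
#'
#' Frames are taken in storage (acquisition) order. The frame interval is not
#' stored in TIFF and must be supplied (default 10 s).
#'
#' @param path TIFF file path.
#' @param frameInterval seconds between frames (default 10).
#' @return A \linkS4class{CaMovie}.
#' @export
readCaMovie <- function(path, frameInterval = 10) {
  if (!file.exists(path)) stop("readCaMovie: file not found: ", path)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                     error = function(e)
                       stop("readCaMovie: cannot read '", path,
                            "' as TIFF (", conditionMessage(e),
                            "); is the file complete?"))
  if (length(frames) < 2L)
    stop("readCaMovie: '", path, "' has a single frame; a time-lapse ",
         "stack with >= 2 frames is required")
  if (length(dim(frames[[1L]])) != 2L)
    stop("readCaMovie: '", path, "' is not single-channel grayscale; ",
         "convert RGB stacks to grayscale before loading")
  d <- dim(frames[[1L]])
  arr <- array(0, dim = c(length(frames), d[1L], d[2L]))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  CaMovie(arr * 65536, frameInterval = frameInterval)
}

#' Write a CaMovie as a multi-frame grayscale TIFF
#'
#' Intensities are stored as 32-bit float scaled by 1/65536 (so any intensity
#' below 65536 round-trips at single precision); \code{\link{readCaMovie}}
#' undoes the scaling.
#'
#' @param movie a \linkS4class{CaMovie}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCaMovie <- function(movie, path) {
  stopifnot(is(movie, "CaMovie"))
  if (max(movie@data) >= 65536)
    stop("writeCaMovie: intensities must be below 65536")
  frames <- lapply(seq_len(dim(movie@data)[1L]),
                   function(f) movie@data[f, , ] / 65536)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write a LabelMask as a 16-bit TIFF plus an ROI table
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param path output TIFF path; the ROI CSV (label, area_px, centroid_row,
#'   centroid_col) is written next to it with suffix "_rois.csv".
#' @return the TIFF path, invisibly.
#' @export
writeLabelMask <- function(mask, path) {
  stopifnot(is(mask, "LabelMask"))
  if (nLabels(mask) > 65535L) stop("writeLabelMask: more than 65535 labels")
  tiff::writeTIFF(labelMatrix(mask) / 65535, path, bits.per.sample = 16L)
  csv <- sub("\\.tiff?$", "", path)
  utils::write.csv(roiTable(mask), paste0(csv, "_rois.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read a LabelMask written by writeLabelMask
#' @param path TIFF path.
#' @return A \linkS4class{LabelMask}.
#' @export
readLabelMask <- function(path) {
  m <- tiff::readTIFF(path)
  LabelMask(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)))
}

#' Write traces as CSV (first column cell_id, then one column per frame)
#'
#' Column headers after cell_id are frame times in seconds.
#'
#' @param ts a \linkS4class{TraceSet}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTraceCSV <- function(ts, path) {
  stopifnot(is(ts, "TraceSet"))
  df <- data.frame(cell_id = cellIds(ts), rawTraces(ts),
                   check.names = FALSE)
  colnames(df) <- c("cell_id", as.character(frameTimes(ts)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace CSV into a TraceSet
#'
#' @param path CSV path (first column cell_id, remaining headers = time in
#'   seconds).
#' @param condition optional condition label.
#' @return A \linkS4class{TraceSet}; the frame interval is inferred from the
#'   time header.
#' @export
readTraceCSV <- function(path, condition = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "cell_id")
    stop("readTraceCSV: first column must be cell_id")
  times <- as.numeric(names(df)[-1L])
  if (any(is.na(times)))
    stop("readTraceCSV: column headers after cell_id must be times in seconds")
  dt <- if (length(times) > 1L) diff(times)[1L] else 10
  TraceSet(as.matrix(df[, -1L, drop = FALSE]), frameInterval = dt,
           cellIds = df$cell_id, condition = condition)
}

#' Write simulation ground truth as CSV
#'
#' One row per cell: cell_id, true_class, semicolon-joined spike frames and
#' amplitudes.
#'
#' @param sim a \linkS4class{CaSimulation}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeGroundTruthCSV <- function(sim, path) {
  gt <- groundTruth(sim)
  df <- data.frame(
    cell_id = gt$cell_id,
    true_class = gt$true_class,
    spike_frames = vapply(gt$spike_frames, paste, character(1),
                          collapse = ";"),
    amplitudes = vapply(gt$amplitudes,
                        function(a) paste(signif(a, 8), collapse = ";"),
                        character(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write/read class boundaries as JSON
#' @param boundaries a \linkS4class{ClassBoundaries}.
#' @param path JSON path.
#' @return the path (write) or a \linkS4class{ClassBoundaries} (read).
#' @export
writeBoundariesJSON <- function(boundaries, path) {
  jsonlite::write_json(
    list(spike_thr = boundaries@spikeThr, amp_thr = boundaries@ampThr,
         silent_max_spikes = boundaries@silentMaxSpikes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBoundariesJSON
#' @export
readBoundariesJSON <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  ClassBoundaries(spikeThr = b$spike_thr, ampThr = b$amp_thr,
                  silentMaxSpikes = b$silent_max_spikes)
}

#' Read a Ct table CSV (gene, condition, replicate, ct)
#'
#' @param path CSV path.
#' @param referenceGene reference gene name stored as an attribute.
#' @return data.frame with attribute "referenceGene".
#' @export
readCtTable <- function(path, referenceGene = "ACTB") {
  df <- utils::read.csv(path)
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("readCtTable: CSV needs columns ", paste(need, collapse = ", "))
  if (!all(is.finite(df$ct))) stop("readCtTable: non-finite Ct values")
  if (!referenceGene %in% df$gene)
    stop("readCtTable: reference gene '", referenceGene, "' absent")
  attr(df, "referenceGene") <- referenceGene
  df
}

#' Read a viability plate CSV (well, dose_um, absorbance, role)
#' @param path CSV path.
#' @return data.frame.
#' @export
readPlateCSV <- function(path) {
  df <- utils::read.csv(path)
  need <- c("well", "dose_um", "absorbance", "role")
  if (!all(need %in% names(df)))
    stop("readPlateCSV: CSV needs columns ", paste(need, collapse = ", "))
  df
}

#' Write/read a simulation configuration as YAML
#' @param config a \code{\link{simConfig}} or pipeline config list.
#' @param path YAML path.
#' @export
writeConfigYAML <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x), path)
  invisible(path)
}

#' @rdname writeConfigYAML
#' @export
readConfigYAML <- function(path) {
  yaml::read_yaml(path)
}
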