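#' @importFrom ggplot2 ggplot aes geom_point geom_raster geom_col geom_boxplot
#'   geom_tile scale_fill_gradientn scale_color_manual scale_fill_manual labs
#'   theme_bw theme element_blank annotate ggsave
NULL

.placeholderPlot <- function(what) {
  warning("renderFigures: no data for ", what, "; writing placeholder")
  ggplot() +
    annotate("text", x = 0, y = 0, label = paste("no data:", what)) +
    theme_bw() + labs(x = NULL, y = NULL)
}

#' Raster plot of population spiking activity
#'
#' One mark per detected spike, cells on the y axis, time in seconds on the
#' x axis.
#'
#' @param raster raster table from \code{\link{buildRaster}} (or a spike
#'   table from \code{\link{detectSpikes}}).
#' @return a ggplot object.
#' @export
plotRaster <- function(raster) {
  if (!nrow(raster)) return(.placeholderPlot("raster"))
  if (!"cell_index" %in% names(raster)) raster <- buildRaster(raster)
  ggplot(raster, aes(x = .data$time_s, y = .data$cell_index)) +
    geom_point(shape = "|", size = 2) +
    labs(x = "time (s)", y = "cell") + theme_bw()
}

#' Heat map of deltaF/F0 time courses
#'
#' @param nts a \linkS4class{NormalizedTraceSet}.
#' @return a ggplot object.
#' @export
plotTraceHeatmap <- function(nts) {
  D <- dff(nts)
  if (!nrow(D)) return(.placeholderPlot("trace heat map"))
  df <- expand.grid(cell = seq_len(nrow(D)), frame = seq_len(ncol(D)))
  df$time_s <- (df$frame - 1) * frameInterval(nts)
  df$dff <- as.vector(D)
  ggplot(df, aes(x = .data$time_s, y = .data$cell, fill = .data$dff)) +
    geom_raster() +
    scale_fill_gradientn(colours = c("black", "darkblue", "yellow", "red"),
                         name = "dF/F0") +
    labs(x = "time (s)", y = "cell") + theme_bw()
}

#' Feature scatter coloured by activity class
#'
#' @param features feature table with an added \code{class} column (or one is
#'   computed from \code{boundaries}).
#' @param boundaries optional \linkS4class{ClassBoundaries} used when
#'   \code{features$class} is absent.
#' @return a ggplot object.
#' @export
plotFeatureScatter <- function(features, boundaries = ClassBoundaries()) {
  if (!nrow(features)) return(.placeholderPlot("feature scatter"))
  if (!"class" %in% names(features))
    features$class <- classifyCells(features, boundaries)
  features$class <- factor(features$class, levels = activityClasses())
  ggplot(features, aes(x = .data$spike_count, y = .data$ca_max,
                       colour = .data$class)) +
    geom_point(size = 2, alpha = 0.8) +
    scale_color_manual(values = classColors(), drop = FALSE) +
    labs(x = "Ca2+ spike count (per 600 s)", y = "Ca2+max (dF/F0)") +
    theme_bw()
}

#' Stacked bars of subpopulation percentages
#'
#' @param profiles profile table from \code{\link{subsampleProfiles}}, or any
#'   data.frame with condition/sample_id plus one column per class.
#' @param by "condition" (mean across repeats, default) or "sample"
#'   (one bar per draw).
#' @return a ggplot object.
#' @export
plotStackedBars <- function(profiles, by = c("condition", "sample")) {
  if (!nrow(profiles)) return(.placeholderPlot("stacked bars"))
  by <- match.arg(by)
  cls <- activityClasses()
  if (by == "condition") {
    agg <- stats::aggregate(profiles[cls],
                            by = list(unit = profiles$condition), mean)
  } else {
    agg <- cbind(unit = profiles$sample_id, profiles[cls])
  }
  long <- stats::reshape(agg, direction = "long", varying = cls,
                         v.names = "percent", timevar = "class",
                         times = cls, idvar = "unit")
  long$class <- factor(long$class, levels = cls)
  ggplot(long, aes(x = .data$unit, y = .data$percent, fill = .data$class)) +
    geom_col(position = "stack") +
    scale_fill_manual(values = classColors(), drop = FALSE) +
    labs(x = NULL, y = "cells (%)") + theme_bw()
}

#' Box plots with 10-90 percent whiskers
#'
#' Boxes are drawn from precomputed \code{\link{boxSummary}} statistics:
#' median, interquartile range and whiskers at the 10th and 90th percentiles.
#'
#' @param values numeric vector of observations.
#' @param group grouping factor (e.g. condition).
#' @param ylab y-axis label.
#' @return a ggplot object.
#' @export
plotBoxSummaries <- function(values, group, ylab = "value") {
  if (!length(values)) return(.placeholderPlot("box plot"))
  parts <- split(values, group)
  stats_ <- do.call(rbind, lapply(names(parts), function(g)
    cbind(group = g, boxSummary(parts[[g]]))))
  ggplot(stats_, aes(x = .data$group)) +
    geom_boxplot(aes(ymin = .data$p10, lower = .data$q1,
                     middle = .data$median, upper = .data$q3,
                     ymax = .data$p90), stat = "identity", width = 0.5) +
    labs(x = NULL, y = ylab) + theme_bw()
}

#' Render the standard figure set of a pipeline run
#'
#' Writes raster plot, deltaF/F0 heat map, feature scatter, stacked bars and
#' spike-count / Ca2+max box plots as PNG files. Empty inputs yield
#' placeholder figures with a warning.
#'
#' @param results list with (any of) elements \code{spikes}, \code{nts},
#'   \code{features} (with class column), \code{profiles}; named per
#'   condition or flat.
#' @param outDir output directory (created if needed).
#' @param width,height figure size in inches.
#' @return character vector of written files.
#' @export
renderFigures <- function(results, outDir, width = 7, height = 5) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  save1 <- function(p, name) {
    f <- file.path(outDir, name)
    ggsave(f, p, width = width, height = height, dpi = 120)
    files <<- c(files, f)
  }
  if (!is.null(results$spikes)) {
    r <- buildRaster(results$spikes,
                     cellIds = if (!is.null(results$nts))
                       cellIds(results$nts) else NULL)
    save1(plotRaster(r), "raster.png")
  }
  if (!is.null(results$nts))
    save1(plotTraceHeatmap(results$nts), "trace_heatmap.png")
  if (!is.null(results$features)) {
    save1(plotFeatureScatter(results$features), "feature_scatter.png")
    if ("condition" %in% names(results$features) &&
        length(unique(results$features$condition)) >= 1L) {
      save1(plotBoxSummaries(results$features$spike_count,
                             results$features$condition,
                             "Ca2+ spike count"), "box_spike_count.png")
      save1(plotBoxSummaries(results$features$ca_max,
                             results$features$condition,
                             "Ca2+max (dF/F0)"), "box_ca_max.png")
    }
  }
  if (!is.null(results$profiles))
    save1(plotStackedBars(results$profiles), "stacked_bars.png")
  files
}
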