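#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper around \code{\link[stats]{kruskal.test}} (rank-based H with
#' tie correction, p from the chi-square distribution with #groups - 1
#' degrees of freedom) that also handles the degenerate all-values-identical
#' case, for which it returns H = 0, p = 1.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with elements H, p, df.
#' @export
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("kruskalWallis: at least two groups are required")
  if (any(lengths(groups) == 0L))
    stop("kruskalWallis: every group must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(pooled) < 3L)
    stop("kruskalWallis: at least 3 observations in total are required")
  df <- length(groups) - 1L
  if (length(unique(pooled)) == 1L)
    return(list(H = 0, p = 1, df = df))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = unname(kt$p.value), df = df)
}

#' Jarque-Bera normality test
#'
#' JB = n/6 (S^2 + (K - 3)^2 / 4) with sample skewness S and kurtosis K
#' (moment estimators); p from the chi-square distribution with 2 degrees of
#' freedom.
#'
#' @param x numeric sample, n >= 8.
#' @return list with elements JB, p, skewness, kurtosis.
#' @export
#' @examples
#' jarqueBera(rnorm(500))
jarqueBera <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("jarqueBera: at least 8 observations are required")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("jarqueBera: degenerate sample (zero variance)")
  S <- mean((x - m)^3) / m2^1.5
  K <- mean((x - m)^4) / m2^2
  JB <- n / 6 * (S^2 + (K - 3)^2 / 4)
  list(JB = JB, p = stats::pchisq(JB, df = 2, lower.tail = FALSE),
       skewness = S, kurtosis = K)
}

#' Box-plot summary with 10-90 percent whiskers
#'
#' Median, quartiles and the 10th/90th percentiles, computed as
#' order-statistics percentiles with linear interpolation
#' (\code{quantile type 7}).
#'
#' @param x numeric sample, n >= 1.
#' @return data.frame with columns median, q1, q3, p10, p90, n; attribute
#'   "quantile_type" records the interpolation convention.
#' @export
#' @examples
#' boxSummary(1:11)
boxSummary <- function(x) {
  x <- as.numeric(x)
  if (!length(x)) stop("boxSummary: empty sample")
  q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE,
                       type = 7)
  out <- data.frame(median = q[3L], q1 = q[2L], q3 = q[4L],
                    p10 = q[1L], p90 = q[5L], n = length(x))
  attr(out, "quantile_type") <- 7L
  out
}

#' 2^-ddCt relative fold change from a Ct table
#'
#' Per replicate, dCt = Ct(target) - Ct(reference); ddCt_i =
#' dCt(treated, i) - mean(dCt(control)); fold_i = 2^-ddCt_i. Reported as the
#' mean fold across treated replicates with its SEM (SEM of the
#' per-replicate folds; set \code{logDomain = TRUE} to average in the ddCt
#' domain and transform the mean instead).
#'
#' @param ctTable data.frame with columns gene, condition, replicate, ct.
#' @param targetGene target gene name.
#' @param referenceGene housekeeping gene used for normalisation (defaults to
#'   the table's "referenceGene" attribute, else "ACTB").
#' @param controlCondition,treatedCondition condition names.
#' @param logDomain average in the ddCt (log2) domain (default FALSE).
#' @return data.frame with columns gene, fold, sem, n_replicates.
#' @export
foldChangeDDCt <- function(ctTable, targetGene,
                           referenceGene = NULL,
                           controlCondition = "no_stress",
                           treatedCondition = "hypoxia",
                           logDomain = FALSE) {
  if (is.null(referenceGene))
    referenceGene <- attr(ctTable, "referenceGene") %||% "ACTB"
  dCt <- function(cond) {
    tg <- ctTable[ctTable$gene == targetGene & ctTable$condition == cond, ]
    rf <- ctTable[ctTable$gene == referenceGene & ctTable$condition == cond, ]
    if (!nrow(tg))
      stop("foldChangeDDCt: no Ct values for gene '", targetGene,
           "' in condition '", cond, "'")
    i <- match(tg$replicate, rf$replicate)
    if (any(is.na(i)))
      stop("foldChangeDDCt: reference gene '", referenceGene,
           "' missing for replicate(s) ",
           paste(tg$replicate[is.na(i)], collapse = ", "),
           " in condition '", cond, "'")
    tg$ct - rf$ct[i]
  }
  ddct <- dCt(treatedCondition) - mean(dCt(controlCondition))
  folds <- 2^(-ddct)
  n <- length(folds)
  if (logDomain) {
    fold <- 2^(-mean(ddct))
    sem <- if (n > 1) fold * log(2) * stats::sd(ddct) / sqrt(n) else 0
  } else {
    fold <- mean(folds)
    sem <- if (n > 1) stats::sd(folds) / sqrt(n) else 0
  }
  data.frame(gene = targetGene, fold = fold, sem = sem, n_replicates = n)
}

#' Blank-subtracted percentage viability from an absorbance plate
#'
#' Per treated well, viability = 100 (A - mean blank) / (mean control - mean
#' blank); reported as mean and SEM per dose. Controls are 100 percent by
#' construction.
#'
#' @param plate data.frame with columns well, dose_um, absorbance, role
#'   (blank / control / treated).
#' @return data.frame with columns dose_um, percent, sem, n_wells.
#' @export
viabilityPercent <- function(plate) {
  need <- c("dose_um", "absorbance", "role")
  if (!all(need %in% names(plate)))
    stop("viabilityPercent: plate needs columns ",
         paste(need, collapse = ", "))
  blank <- plate$absorbance[plate$role == "blank"]
  control <- plate$absorbance[plate$role == "control"]
  if (!length(blank) || !length(control))
    stop("viabilityPercent: plate needs at least one blank and one control")
  b <- mean(blank); c0 <- mean(control)
  if (c0 <= b)
    stop("viabilityPercent: control absorbance must exceed the blank")
  treated <- plate[plate$role == "treated", ]
  res <- lapply(split(treated, treated$dose_um), function(d) {
    pct <- 100 * (d$absorbance - b) / (c0 - b)
    data.frame(dose_um = d$dose_um[1L], percent = mean(pct),
               sem = if (nrow(d) > 1) stats::sd(pct) / sqrt(nrow(d)) else 0,
               n_wells = nrow(d))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$dose_um), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
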