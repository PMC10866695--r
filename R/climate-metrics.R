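#' Mean annual precipitation
#'
#' Per pixel, the mean over years of the annual (12-month) precipitation
#' totals.
#'
#' @param precip a precipitation [ClimateCube-class].
#' @return a [MetricMap-class] with metric \code{"MAP"} (mm yr-1).
#' @examples
#' g <- gridSpec(2, 2)
#' cube <- climateCube(array(100, c(4, 3, 12)), 2001:2003, "precip", g)
#' mapValues(computeMAP(cube))  # 1200 everywhere
#' @export
computeMAP <- function(precip) {
  stopifnot(precip@varname == "precip")
  totals <- annualTotals(precip)
  vals <- rowMeans(totals)
  metricMap(cellsToMatrix(vals, precip@grid), "MAP", precip@grid,
            referencePeriod = range(precip@years))
}

#' Maximum cumulative water deficit (MCWD)
#'
#' Within each year the monthly water deficit is accumulated as
#' WD_1 = min(0, P_1 - E), WD_m = min(0, WD_{m-1} + P_m - E), with E a
#' fixed reference evapotranspiration (default 100 mm month-1, the
#' conventional tropical value). The year's MCWD is the most negative WD;
#' it is always <= 0, and equals 0 only if no month's running deficit goes
#' negative. The pixel value is the mean over years (\code{perYear =
#' FALSE}) or the full per-year series (\code{perYear = TRUE}, used by
#' drought detection).
#'
#' @param precip a precipitation [ClimateCube-class].
#' @param evapRef reference evapotranspiration, mm month-1; must be >= 0.
#' @param perYear return the \code{[nCells, nYears]} series instead of the
#'   climatological map.
#' @return a [MetricMap-class] with metric \code{"MCWD"} (mm), or the
#'   per-year matrix.
#' @export
computeMCWD <- function(precip, evapRef = 100, perYear = FALSE) {
  stopifnot(precip@varname == "precip")
  if (evapRef < 0) stop("reference evapotranspiration must be >= 0")
  v <- precip@values
  n <- dim(v)[1]; ny <- dim(v)[2]
  mcwd <- matrix(0, n, ny)
  wd <- matrix(0, n, ny)
  for (m in 1:12) {
    wd <- pmin(0, wd + v[, , m] - evapRef)
    mcwd <- pmin(mcwd, wd)
  }
  mcwd[!precip@mask, ] <- NA_real_
  if (perYear) {
    colnames(mcwd) <- precip@years
    return(mcwd)
  }
  metricMap(cellsToMatrix(rowMeans(mcwd), precip@grid), "MCWD",
            precip@grid, referencePeriod = range(precip@years))
}

#' Dry-season length (DSL)
#'
#' Number of climatological months (mean over years per calendar month)
#' with precipitation strictly below the dry-month threshold
#' (conventionally 100 mm). Integer in [0, 12]; non-increasing as the
#' threshold decreases.
#'
#' @param precip a precipitation [ClimateCube-class].
#' @param dryMonthThreshold mm; months strictly below count as dry.
#' @return a [MetricMap-class] with metric \code{"DSL"} (months).
#' @export
computeDSL <- function(precip, dryMonthThreshold = 100) {
  stopifnot(precip@varname == "precip")
  clim <- apply(precip@values, c(1, 3), mean)  # [nCells, 12]
  dsl <- rowSums(clim < dryMonthThreshold)
  dsl[!precip@mask] <- NA_real_
  metricMap(cellsToMatrix(dsl, precip@grid), "DSL", precip@grid,
            referencePeriod = range(precip@years))
}

#' Dry-season mean temperature series
#'
#' Per pixel and year, the mean temperature over the dry-season months
#' (July-October by default). Years with any missing month are masked.
#'
#' @param temp a temperature [ClimateCube-class].
#' @param months integer month indices, default \code{7:10}.
#' @return numeric matrix \code{[nCells, nYears]} (deg C), year columns
#'   named.
#' @export
drySeasonTemperature <- function(temp, months = 7:10) {
  stopifnot(temp@varname == "temp", all(months %in% 1:12))
  sub <- temp@values[, , months, drop = FALSE]
  out <- rowSums(sub, dims = 2) / length(months)
  out[apply(is.na(sub), c(1, 2), any)] <- NA_real_
  out[!temp@mask, ] <- NA_real_
  colnames(out) <- temp@years
  out
}

#' Count extreme drought events from an annual MCWD series
#'
#' A year is an extreme drought when its MCWD is at least
#' \code{anomalySd} standard deviations more negative than the reference
#' mean. Counts are capped at \code{maxEvents}. The reference mean/sd come
#' from the analysis window itself (\code{reference = "window"}), from the
#' full series (\code{"full"}), or can be supplied directly.
#'
#' @param mcwdYearly numeric matrix \code{[nCells, nYears]} (or a single
#'   series) as returned by \code{computeMCWD(..., perYear = TRUE)}.
#' @param years integer years labelling the columns.
#' @param windowYears length-2 analysis period, default \code{c(2001,
#'   2018)} clipped to the available years.
#' @param anomalySd anomaly threshold in standard deviations (> 0).
#' @param reference \code{"window"} or \code{"full"} baseline.
#' @param refMean,refSd optional explicit baselines (vectors per cell).
#' @param maxEvents cap on the per-pixel count (default 5).
#' @return integer matrix/vector of event counts in \code{[0, maxEvents]};
#'   pixels with zero reference sd report 0 events.
#' @export
detectDroughtEvents <- function(mcwdYearly, years,
                                windowYears = c(2001, 2018),
                                anomalySd = 2,
                                reference = c("window", "full"),
                                refMean = NULL, refSd = NULL,
                                maxEvents = 5L) {
  reference <- match.arg(reference)
  if (anomalySd <= 0) stop("anomalySd must be > 0")
  if (is.vector(mcwdYearly)) mcwdYearly <- matrix(mcwdYearly, nrow = 1)
  stopifnot(ncol(mcwdYearly) == length(years))
  inWin <- years >= windowYears[1] & years <= windowYears[2]
  if (sum(inWin) < 5L) stop("analysis window must contain >= 5 years")
  win <- mcwdYearly[, inWin, drop = FALSE]
  base <- if (reference == "window") win else mcwdYearly
  if (is.null(refMean)) refMean <- rowMeans(base)
  if (is.null(refSd)) refSd <- apply(base, 1, stats::sd)
  thr <- refMean - anomalySd * refSd
  counts <- rowSums(win <= thr)
  counts[refSd == 0 | !is.finite(refSd)] <- 0
  as.integer(pmin(counts, maxEvents))
}
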