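#' Ordinary least squares trend of an annual series
#'
#' Fits y = a + b * year by OLS and reports the two-sided p-value of the
#' slope's t statistic. Significance is screened at \code{alpha}
#' (default 0.1, matching the P < 0.1 criterion used for all per-pixel
#' trend maps); no multiple-testing correction is applied.
#'
#' @param y numeric annual values.
#' @param years numeric calendar years (same length).
#' @param alpha significance level.
#' @return list with \code{slope}, \code{intercept} (value at year 0),
#'   \code{pValue}, \code{significant}. Fewer than 3 finite points gives
#'   all-NA; zero variance in y gives slope 0 with undefined p (flagged
#'   not significant).
#' @examples
#' fitTrend(0.03 * (1981:2020 - 1981) + 20, 1981:2020)$slope
#' @export
fitTrend <- function(y, years, alpha = 0.1) {
  ok <- is.finite(y) & is.finite(years)
  y <- y[ok]; x <- years[ok]
  n <- length(y)
  if (n < 3L || stats::var(x) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_,
                pValue = NA_real_, significant = FALSE))
  }
  if (stats::var(y) == 0) {
    return(list(slope = 0, intercept = y[1], pValue = NA_real_,
                significant = FALSE))
  }
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- sum(xc * y) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  p <- if (se == 0) 0 else 2 * stats::pt(-abs(slope / se), df = n - 2)
  list(slope = slope, intercept = intercept, pValue = p,
       significant = is.finite(p) && p < alpha)
}

#' Per-pixel OLS trend map
#'
#' Vectorised OLS of an annual series against calendar year for every
#' pixel at once (the per-pixel analogue of [fitTrend()], to which it is
#' numerically identical).
#'
#' @param yearMatrix numeric \code{[nCells, nYears]} matrix of annual
#'   values (e.g. annual rainfall totals or dry-season mean temperature).
#' @param years integer calendar years.
#' @param grid a [GridSpec-class].
#' @param alpha significance level (default 0.1).
#' @param units units of the series.
#' @return a [TrendMap-class].
#' @export
fitTrendMap <- function(yearMatrix, years, grid, alpha = 0.1, units = "") {
  stopifnot(ncol(yearMatrix) == length(years),
            nrow(yearMatrix) == nCells(grid))
  n <- length(years)
  if (n < 3L) stop("need >= 3 years for a trend")
  x <- as.numeric(years)
  xc <- x - mean(x)
  sxx <- sum(xc^2)

  ok <- rowSums(!is.finite(yearMatrix)) == 0
  Y <- yearMatrix
  Y[!ok, ] <- 0

  slope <- as.vector(Y %*% xc) / sxx
  ybar <- rowMeans(Y)
  intercept <- ybar - slope * mean(x)
  fitted <- outer(intercept, rep(1, n)) + outer(slope, x)
  rss <- rowSums((Y - fitted)^2)
  s2 <- rss / (n - 2)
  se <- sqrt(s2 / sxx)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[se == 0 & slope != 0] <- 0          # perfect non-constant fit
  degenerate <- rowSums((Y - ybar)^2) == 0
  slope[degenerate] <- 0
  p[degenerate] <- NA_real_             # constant series: never significant
  slope[!ok] <- NA_real_; intercept[!ok] <- NA_real_; p[!ok] <- NA_real_

  new("TrendMap",
    slope = cellsToMatrix(slope, grid),
    intercept = cellsToMatrix(intercept, grid),
    pValue = cellsToMatrix(p, grid),
    alpha = alpha, units = units, grid = grid
  )
}

#' Extrapolate a metric to 2050 along significant trends
#'
#' Where a pixel's trend is significant, the 2050 value is the fitted
#' regression line evaluated at the target year (intercept + slope x
#' 2050); elsewhere the present-day value is kept. Evaluating the fitted
#' line (rather than adding slope x delta-t to the last noisy
#' observation) makes the projection deterministic and noise-free.
#'
#' @param trend a [TrendMap-class].
#' @param baseMetric a [MetricMap-class] on the same grid (present-day
#'   values, used where the trend is not significant).
#' @param targetYear default 2050.
#' @param maxAbsSlope sanity bound on |slope| (units yr-1, default 25,
#'   appropriate for annual-rainfall trends in mm yr-1 per year); a
#'   significant slope exceeding it aborts. Use \code{Inf} to disable.
#' @param floorAtZero clip projected values at 0 (sensible for MAP).
#' @return a [MetricMap-class] for the target year.
#' @export
extrapolateTo2050 <- function(trend, baseMetric, targetYear = 2050,
                              maxAbsSlope = 25, floorAtZero = TRUE) {
  assertSameGrid(trend@grid, gridOf(baseMetric))
  sig <- isSignificant(trend)
  bad <- sig & abs(trend@slope) > maxAbsSlope
  if (any(bad, na.rm = TRUE)) {
    stop("slope magnitude guard: ", sum(bad, na.rm = TRUE),
         " significant pixels exceed |slope| = ", maxAbsSlope)
  }
  vals <- mapValues(baseMetric)
  proj <- trend@intercept + trend@slope * targetYear
  vals[sig] <- proj[sig]
  if (floorAtZero) vals <- pmax(vals, 0)
  metricMap(vals, metricName(baseMetric), gridOf(baseMetric),
            units = baseMetric@units,
            referencePeriod = c(targetYear, targetYear))
}
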