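#' @include grid.R
NULL

#' Per-pixel climate metric map
#'
#' A single-band raster holding one climate metric per pixel. Metric names
#' follow the field's conventions: \code{"MAP"} (mean annual precipitation,
#' mm yr-1, >= 0), \code{"MCWD"} (maximum cumulative water deficit, mm,
#' <= 0), \code{"DSL"} (dry-season length, months, in [0, 12]; integer
#' when produced by [computeDSL()], fractional allowed for synthetic
#' climatological axes),
#' \code{"TDRY"} (dry-season mean temperature, deg C). Anything else is
#' stored without metric-specific checks. NA marks masked pixels.
#'
#' @slot values numeric matrix (nrow x ncol of \code{grid}).
#' @slot metric character metric identifier.
#' @slot units character unit string.
#' @slot referencePeriod numeric length-2 year range the metric refers to.
#' @slot grid a [GridSpec-class].
#' @export
setClass("MetricMap",
  representation(
    values = "matrix", metric = "character", units = "character",
    referencePeriod = "numeric", grid = "GridSpec"
  )
)

setValidity("MetricMap", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != object@grid@nrow || ncol(v) != object@grid@ncol)
    msg <- c(msg, "values dimensions do not match grid")
  fin <- v[is.finite(v)]
  if (identical(object@metric, "MAP") && any(fin < 0))
    msg <- c(msg, "MAP must be >= 0")
  if (identical(object@metric, "MCWD") && any(fin > 1e-9))
    msg <- c(msg, "MCWD must be <= 0")
  if (identical(object@metric, "DSL") && (any(fin < 0) || any(fin > 12)))
    msg <- c(msg, "DSL must lie in [0, 12]")
  if (length(msg)) msg else TRUE
})

#' Construct a MetricMap
#'
#' @param values numeric matrix on \code{grid}.
#' @param metric metric name (see [MetricMap-class]).
#' @param grid a [GridSpec-class].
#' @param units unit string; defaults chosen from \code{metric}.
#' @param referencePeriod year range, default \code{c(1981, 2020)}.
#' @return a [MetricMap-class].
#' @export
metricMap <- function(values, metric, grid,
                      units = defaultUnits(metric),
                      referencePeriod = c(1981, 2020)) {
  new("MetricMap",
    values = values, metric = metric, units = units,
    referencePeriod = as.numeric(referencePeriod), grid = grid
  )
}

defaultUnits <- function(metric) {
  switch(metric,
    MAP = "mm yr-1", MCWD = "mm", DSL = "months", TDRY = "deg C",
    treecover = "%", ""
  )
}

#' Accessors for raster-backed classes
#'
#' \code{mapValues} returns the value matrix, \code{gridOf} the
#' [GridSpec-class], \code{metricName} the metric identifier.
#'
#' @param x a MetricMap (or, for \code{gridOf}, any class with a grid slot).
#' @export
mapValues <- function(x) x@values

#' @rdname mapValues
#' @export
gridOf <- function(x) x@grid

#' @rdname mapValues
#' @export
metricName <- function(x) x@metric

setMethod("show", "MetricMap", function(object) {
  fin <- object@values[is.finite(object@values)]
  cat("MetricMap <", object@metric, "> [", object@units, "] ",
    object@grid@nrow, "x", object@grid@ncol, " pixels, ",
    sum(!is.finite(object@values)), " masked\n",
    sep = ""
  )
  if (length(fin)) {
    cat(sprintf(
      "  range %.3g .. %.3g, mean %.4g; reference %d-%d\n",
      min(fin), max(fin), mean(fin),
      object@referencePeriod[1], object@referencePeriod[2]
    ))
  }
})

#' Per-pixel trend regression map
#'
#' Ordinary-least-squares slope, intercept (at calendar year 0) and
#' two-sided p-value of a per-pixel regression of an annual series against
#' calendar year. A pixel is \emph{significant} iff its p-value is below
#' \code{alpha} (default 0.1, the screening level used throughout).
#'
#' @slot slope,intercept,pValue numeric matrices on \code{grid}.
#' @slot alpha numeric significance level.
#' @slot units units of the underlying series (slope is units per year).
#' @slot grid a [GridSpec-class].
#' @export
setClass("TrendMap",
  representation(
    slope = "matrix", intercept = "matrix", pValue = "matrix",
    alpha = "numeric", units = "character", grid = "GridSpec"
  )
)

setValidity("TrendMap", function(object) {
  msg <- character()
  d <- c(object@grid@nrow, object@grid@ncol)
  for (nm in c("slope", "intercept", "pValue")) {
    m <- slot(object, nm)
    if (!all(dim(m) == d)) msg <- c(msg, paste(nm, "dims do not match grid"))
  }
  p <- object@pValue[is.finite(object@pValue)]
  if (any(p < 0 | p > 1)) msg <- c(msg, "p-values outside [0,1]")
  if (!(length(object@alpha) == 1L && object@alpha > 0 && object@alpha < 1))
    msg <- c(msg, "alpha must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Significance mask of a TrendMap
#'
#' @param trend a [TrendMap-class].
#' @return logical matrix, TRUE where p < alpha; FALSE where the p-value is
#'   undefined (degenerate fits are never significant).
#' @export
isSignificant <- function(trend) {
  sig <- trend@pValue < trend@alpha
  sig[!is.finite(trend@pValue)] <- FALSE
  sig
}

setMethod("show", "TrendMap", function(object) {
  sig <- isSignificant(object)
  cat("TrendMap [", object@units, " yr-1] ",
    object@grid@nrow, "x", object@grid@ncol, " pixels, ",
    sprintf("%.1f%%", 100 * mean(sig)), " significant at alpha=",
    object@alpha, "\n",
    sep = ""
  )
})
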