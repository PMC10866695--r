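#' @include grid.R
NULL

#' Ecosystem stability class map
#'
#' Per-pixel partition into stable forest (code 0), bistable (1) and
#' stable savanna (2) from annual rainfall relative to the lower/upper
#' critical thresholds; NA marks masked pixels. The integer codes double
#' as the class scores of the transition-potential index.
#'
#' @slot classes integer matrix (0/1/2/NA) on \code{grid}.
#' @slot lower,upper thresholds (mm yr-1) used.
#' @slot epoch \code{"current"} or \code{"2050"}.
#' @slot grid a [GridSpec-class].
#' @export
setClass("StabilityClassMap",
  representation(
    classes = "matrix", lower = "numeric", upper = "numeric",
    epoch = "character", grid = "GridSpec"
  )
)

setValidity("StabilityClassMap", function(object) {
  msg <- character()
  cl <- object@classes
  if (nrow(cl) != object@grid@nrow || ncol(cl) != object@grid@ncol)
    msg <- c(msg, "classes dimensions do not match grid")
  vals <- cl[!is.na(cl)]
  if (!all(vals %in% 0:2)) msg <- c(msg, "classes must be 0, 1, 2 or NA")
  if (object@lower >= object@upper) msg <- c(msg, "lower must be < upper")
  if (length(msg)) msg else TRUE
})

#' @rdname mapValues
#' @export
classValues <- function(x) x@classes

classLabels <- c("stable_forest", "bistable", "stable_savanna")

setMethod("show", "StabilityClassMap", function(object) {
  f <- classFractions(object)
  cat("StabilityClassMap (", object@epoch, "), thresholds ",
    object@lower, "/", object@upper, " mm: ",
    paste(sprintf("%s %.1f%%", names(f), 100 * f), collapse = ", "),
    "\n",
    sep = ""
  )
})

#' Areal class fractions
#'
#' @param classMap a [StabilityClassMap-class].
#' @param mask optional logical matrix restricting the area.
#' @return named fractions of unmasked pixels per class (sums to 1).
#' @export
classFractions <- function(classMap, mask = NULL) {
  cl <- classMap@classes
  if (!is.null(mask)) cl[!mask] <- NA
  n <- sum(!is.na(cl))
  f <- vapply(0:2, function(k) sum(cl == k, na.rm = TRUE) / n, numeric(1))
  names(f) <- classLabels
  f
}

#' Classify pixels into stability classes from annual rainfall
#'
#' Half-open bins with the wetter class winning on the boundary:
#' MAP < lower gives stable savanna, lower <= MAP < upper gives bistable,
#' MAP >= upper gives stable forest. Non-finite rainfall is masked. The
#' default thresholds are 1000 and 1800 mm yr-1; thresholds recovered by
#' [extractThresholds()] can be passed instead for a self-consistent
#' pipeline.
#'
#' @param mapField a [MetricMap-class] with metric \code{"MAP"}.
#' @param lower,upper critical thresholds (mm yr-1), lower < upper.
#' @param epoch label, default \code{"current"}.
#' @return a [StabilityClassMap-class].
#' @examples
#' g <- gridSpec(1, 3)
#' m <- metricMap(matrix(c(900, 1400, 1800), 1), "MAP", g)
#' classValues(classifyStability(m))  # 2 1 0
#' @export
classifyStability <- function(mapField, lower = 1000, upper = 1800,
                              epoch = "current") {
  stopifnot(metricName(mapField) == "MAP", lower < upper)
  v <- mapValues(mapField)
  cl <- matrix(NA_integer_, nrow(v), ncol(v))
  cl[v >= upper] <- 0L
  cl[v >= lower & v < upper] <- 1L
  cl[v < lower] <- 2L
  cl[!is.finite(v)] <- NA_integer_
  new("StabilityClassMap",
    classes = cl, lower = lower, upper = upper, epoch = epoch,
    grid = gridOf(mapField)
  )
}

#' Project stability classes to 2050 along significant rainfall trends
#'
#' Rainfall is extrapolated to 2050 with [extrapolateTo2050()] on pixels
#' with significant trends only (others keep their present-day value),
#' classes are recomputed, and the areal fractions of every current-to-
#' 2050 class transition are summarised over the analysis mask.
#'
#' @param mapNow present-day MAP [MetricMap-class].
#' @param rainfallTrend a [TrendMap-class] of annual rainfall totals.
#' @param lower,upper thresholds (mm yr-1).
#' @param biomeMask optional logical matrix restricting the transition
#'   summary.
#' @param targetYear default 2050.
#' @return list with \code{classMap2050} ([StabilityClassMap-class]),
#'   \code{map2050} ([MetricMap-class]) and \code{transitions} (a
#'   data.frame of from/to class fractions over the mask).
#' @export
projectStability2050 <- function(mapNow, rainfallTrend,
                                 lower = 1000, upper = 1800,
                                 biomeMask = NULL, targetYear = 2050) {
  assertSameGrid(gridOf(mapNow), rainfallTrend@grid)
  map2050 <- extrapolateTo2050(rainfallTrend, mapNow,
                               targetYear = targetYear)
  now <- classifyStability(mapNow, lower, upper, epoch = "current")
  fut <- classifyStability(map2050, lower, upper,
                           epoch = as.character(targetYear))
  a <- now@classes; b <- fut@classes
  if (!is.null(biomeMask)) {
    a[!biomeMask] <- NA
    b[!biomeMask] <- NA
  }
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  transitions <- expand.grid(from = classLabels, to = classLabels,
                             KEEP.OUT.ATTRS = FALSE)
  transitions$fraction <- mapply(function(f, t) {
    sum(a[ok] == (match(f, classLabels) - 1L) &
        b[ok] == (match(t, classLabels) - 1L)) / n
  }, transitions$from, transitions$to)
  list(classMap2050 = fut, map2050 = map2050, transitions = transitions)
}
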