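#' Synthetic biome configuration
#'
#' Parameters of the synthetic bistable tree-cover generator. Tree cover
#' is drawn conditionally on a climate metric: below the dry-side
#' threshold only the low-cover (savanna) mode exists, beyond the wet-side
#' threshold only the high-cover (forest) mode, and in between a pixel is
#' in the forest mode with probability \code{bistableForestWeight} - a
#' cross-sectional mixture representation of conditional bimodality (the
#' only feature the potential analysis consumes; hysteresis history is not
#' modelled).
#'
#' Presets encode the bistability ranges the potential analysis is
#' expected to recover: annual rainfall 1000-1800 mm yr-1, maximum
#' cumulative water deficit -450..-350 mm, dry-season length 5-8 months.
#' Mode means/sds (85 +/- 8 % forest, 20 +/- 10 % savanna) keep the two
#' modes separable at the 0.005 density floor for windows of a few
#' thousand pixels.
#'
#' @param variable climate axis: \code{"map"}, \code{"mcwd"} or
#'   \code{"dsl"}; sets the metric range, thresholds and orientation.
#' @param gridShape integer c(rows, cols); default 250 x 400 = 1e5 pixels.
#' @param pixelSize degrees.
#' @param metricRange numeric c(min, max) spanned across the grid.
#' @param lowerThreshold,upperThreshold bistability edges in metric units
#'   (numerically lower < upper).
#' @param forestModeMean,forestModeSd,savannaModeMean,savannaModeSd tree
#'   cover mode parameters (%).
#' @param bistableForestWeight probability a bistable pixel is forested.
#' @param wetterIsLarger TRUE if larger metric values mean wetter (MAP,
#'   MCWD); FALSE for DSL where longer dry seasons are drier.
#' @param seed integer RNG seed.
#' @return a list of class \code{"BiomeConfig"}.
#' @export
biomeConfig <- function(variable = c("map", "mcwd", "dsl"),
                        gridShape = c(250L, 400L),
                        pixelSize = 0.05,
                        metricRange = NULL,
                        lowerThreshold = NULL,
                        upperThreshold = NULL,
                        forestModeMean = 85, forestModeSd = 8,
                        savannaModeMean = 20, savannaModeSd = 10,
                        bistableForestWeight = 0.5,
                        wetterIsLarger = NULL,
                        seed = 1L) {
  variable <- match.arg(variable)
  preset <- switch(variable,
    map  = list(range = c(0, 3000), thr = c(1000, 1800), wet = TRUE),
    mcwd = list(range = c(-800, 0), thr = c(-450, -350), wet = TRUE),
    dsl  = list(range = c(0, 12),   thr = c(5, 8),       wet = FALSE)
  )
  cfg <- list(
    variable = variable,
    gridShape = as.integer(gridShape),
    pixelSize = pixelSize,
    metricRange = if (is.null(metricRange)) preset$range else metricRange,
    lowerThreshold = if (is.null(lowerThreshold)) preset$thr[1] else lowerThreshold,
    upperThreshold = if (is.null(upperThreshold)) preset$thr[2] else upperThreshold,
    forestModeMean = forestModeMean, forestModeSd = forestModeSd,
    savannaModeMean = savannaModeMean, savannaModeSd = savannaModeSd,
    bistableForestWeight = bistableForestWeight,
    wetterIsLarger = if (is.null(wetterIsLarger)) preset$wet else wetterIsLarger,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$lowerThreshold < cfg$upperThreshold,
    cfg$forestModeMean > cfg$savannaModeMean,
    cfg$forestModeMean >= 0, cfg$forestModeMean <= 100,
    cfg$savannaModeMean >= 0, cfg$savannaModeMean <= 100,
    cfg$bistableForestWeight >= 0, cfg$bistableForestWeight <= 1,
    diff(cfg$metricRange) > 0
  )
  class(cfg) <- "BiomeConfig"
  cfg
}

#' Generate the climate-metric field of a synthetic biome
#'
#' Lays the configured metric range across the grid as a west-to-east
#' gradient with within-column uniform jitter, so the marginal metric
#' distribution is uniform over \code{metricRange} while keeping spatial
#' structure (wet and dry sides of the domain).
#'
#' @param cfg a [biomeConfig()].
#' @param grid optional [GridSpec-class]; built from \code{cfg} if absent.
#' @return a [MetricMap-class] with the metric implied by
#'   \code{cfg$variable}.
#' @export
simulateMetricField <- function(cfg, grid = NULL) {
  if (is.null(grid)) {
    grid <- gridSpec(cfg$gridShape[1], cfg$gridShape[2],
                     pixelSize = cfg$pixelSize)
  }
  set.seed(cfg$seed)
  nr <- grid@nrow; nc <- grid@ncol
  colPos <- matrix(rep(seq_len(nc) - 1L, each = nr), nrow = nr)
  u <- (colPos + matrix(stats::runif(nr * nc), nrow = nr)) / nc
  vals <- cfg$metricRange[1] + u * diff(cfg$metricRange)
  # the DSL axis stays continuous here (an effective climatological
  # dry-season length); computeDSL() outputs are integer month counts
  metric <- switch(cfg$variable, map = "MAP", mcwd = "MCWD", dsl = "DSL")
  metricMap(vals, metric, grid)
}

#' Generate a synthetic bistable tree-cover field
#'
#' Draws per-pixel tree cover from the savanna mode, the forest mode, or
#' the bistable two-component mixture, according to where the pixel's
#' climate metric lies relative to the configured thresholds. Values are
#' clipped to [0, 100] %. Deterministic under \code{cfg$seed}.
#'
#' @param cfg a [biomeConfig()].
#' @param metricField a [MetricMap-class] on the biome grid, e.g. from
#'   [simulateMetricField()].
#' @return a [MetricMap-class] with metric \code{"treecover"}.
#' @export
simulateTreeCover <- function(cfg, metricField) {
  m <- mapValues(metricField)
  if (length(m) == 0L) stop("degenerate grid: zero pixels")
  if (any(!is.finite(m))) stop("metric field must be finite")
  if (cfg$lowerThreshold >= cfg$metricRange[2] ||
      cfg$upperThreshold <= cfg$metricRange[1]) {
    stop("thresholds outside the metric range: no bistable zone representable")
  }
  # orient so that 'wet' always means larger
  wet <- if (cfg$wetterIsLarger) m else -m
  lo <- if (cfg$wetterIsLarger) cfg$lowerThreshold else -cfg$upperThreshold
  hi <- if (cfg$wetterIsLarger) cfg$upperThreshold else -cfg$lowerThreshold

  set.seed(cfg$seed + 1L)
  n <- length(m)
  inForest <- wet >= hi
  inSavanna <- wet < lo
  bistable <- !inForest & !inSavanna
  pickForest <- inForest |
    (bistable & stats::runif(n) < cfg$bistableForestWeight)
  tc <- numeric(n)
  tc[pickForest] <- stats::rnorm(sum(pickForest), cfg$forestModeMean,
                                 cfg$forestModeSd)
  tc[!pickForest] <- stats::rnorm(sum(!pickForest), cfg$savannaModeMean,
                                  cfg$savannaModeSd)
  tc <- pmin(100, pmax(0, tc))
  metricMap(matrix(tc, nrow = nrow(m)), "treecover", gridOf(metricField),
            referencePeriod = c(2001, 2001))
}

#' Generate a full synthetic biome
#'
#' Convenience wrapper producing the metric field and the conditional
#' tree-cover field in one call.
#'
#' @param cfg a [biomeConfig()].
#' @return list with elements \code{metric} and \code{treeCover}
#'   ([MetricMap-class]) plus \code{truth} (the threshold pair encoded in
#'   the generator).
#' @examples
#' biome <- simulateBiome(biomeConfig("map", gridShape = c(50, 80)))
#' biome$truth
#' @export
simulateBiome <- function(cfg) {
  metric <- simulateMetricField(cfg)
  tc <- simulateTreeCover(cfg, metric)
  list(
    metric = metric, treeCover = tc,
    truth = list(
      lowerThreshold = cfg$lowerThreshold,
      upperThreshold = cfg$upperThreshold,
      variable = cfg$variable
    )
  )
}
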