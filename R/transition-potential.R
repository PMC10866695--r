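#' @include grid.R
NULL

#' Transition-potential index configuration
#'
#' Constants of the additive transition-potential index: the dry-season
#' temperature slope (deg C yr-1) enters multiplied by 10 where
#' significant (0 elsewhere); the projected 2050 stability class scores 0
#' (stable forest), 1 (bistable) or 2 (stable savanna); each extreme
#' drought event adds 0.2 (0-5 events); pixels within 10 km of a road add
#' 1; pixels inside protected areas or Indigenous territories subtract 1.
#' With observed slopes the index spans roughly -1 (low potential) to 4
#' (very high potential).
#'
#' @param tempSlopeFactor multiplier on the significant temperature
#'   slope, default 10.
#' @param classScores named numeric scores for the three classes.
#' @param droughtWeight per-event weight, default 0.2.
#' @param roadBufferKm road-proximity buffer, default 10 km.
#' @param roadScore,governanceScore additive scores, default +1 / -1.
#' @param categoryRule \code{"text"} (low <= 1 < moderate <= 2 < high,
#'   reproducing the cumulative more-than-1 / more-than-2 disturbance
#'   logic) or \code{"figure"} (low < 0, moderate 1..2, high > 2, with
#'   the unlabelled [0, 1) interval mapped to low).
#' @return list of class \code{"TPConfig"}.
#' @export
tpConfig <- function(tempSlopeFactor = 10,
                     classScores = c(stable_forest = 0, bistable = 1,
                                     stable_savanna = 2),
                     droughtWeight = 0.2,
                     roadBufferKm = 10,
                     roadScore = 1, governanceScore = -1,
                     categoryRule = c("text", "figure")) {
  stopifnot(
    is.finite(tempSlopeFactor), is.finite(droughtWeight),
    is.finite(roadScore), is.finite(governanceScore),
    roadBufferKm > 0, length(classScores) == 3L
  )
  structure(
    list(
      tempSlopeFactor = tempSlopeFactor, classScores = classScores,
      droughtWeight = droughtWeight, roadBufferKm = roadBufferKm,
      roadScore = roadScore, governanceScore = governanceScore,
      categoryRule = match.arg(categoryRule)
    ),
    class = "TPConfig"
  )
}

#' Disturbance stack feeding the transition-potential index
#'
#' All layers on one shared grid: the dry-season temperature trend, the
#' projected 2050 stability classes, drought-event counts (0-5), the
#' road-proximity mask, the protection mask, the deforestation mask, and
#' the savanna-biome mask (deforested and savanna pixels are excluded
#' from the index).
#'
#' @slot tempTrend a [TrendMap-class].
#' @slot stability2050 a [StabilityClassMap-class].
#' @slot droughtCounts integer matrix in [0, 5].
#' @slot roadNear,protected,deforested,savannaBiome logical matrices.
#' @slot grid a [GridSpec-class].
#' @export
setClass("DisturbanceStack",
  representation(
    tempTrend = "TrendMap", stability2050 = "StabilityClassMap",
    droughtCounts = "matrix", roadNear = "matrix", protected = "matrix",
    deforested = "matrix", savannaBiome = "matrix", grid = "GridSpec"
  )
)

setValidity("DisturbanceStack", function(object) {
  msg <- character()
  g <- object@grid
  dimOk <- function(m) nrow(m) == g@nrow && ncol(m) == g@ncol
  for (nm in c("droughtCounts", "roadNear", "protected", "deforested",
               "savannaBiome")) {
    if (!dimOk(slot(object, nm)))
      msg <- c(msg, paste0("layer '", nm, "' does not match the grid"))
  }
  if (!sameGrid(object@tempTrend@grid, g))
    msg <- c(msg, "layer 'tempTrend' does not match the grid")
  if (!sameGrid(object@stability2050@grid, g))
    msg <- c(msg, "layer 'stability2050' does not match the grid")
  dc <- object@droughtCounts
  dcv <- dc[!is.na(dc)]
  if (any(dcv < 0 | dcv > 5 | dcv != round(dcv)))
    msg <- c(msg, "droughtCounts must be integers in [0, 5]")
  if (length(msg)) msg else TRUE
})

#' Construct a DisturbanceStack
#'
#' @param tempTrend,stability2050,droughtCounts,roadNear,protected,deforested
#'   the index layers (see [DisturbanceStack-class]). All are required;
#'   a missing layer raises an error naming it.
#' @param savannaBiome logical matrix, default all FALSE.
#' @param grid a [GridSpec-class], default taken from \code{tempTrend}.
#' @return a [DisturbanceStack-class].
#' @export
disturbanceStack <- function(tempTrend, stability2050, droughtCounts,
                             roadNear, protected, deforested,
                             savannaBiome = NULL, grid = NULL) {
  if (missing(tempTrend)) stop("missing disturbance layer: 'tempTrend'")
  if (missing(stability2050))
    stop("missing disturbance layer: 'stability2050'")
  if (missing(droughtCounts))
    stop("missing disturbance layer: 'droughtCounts'")
  if (missing(roadNear)) stop("missing disturbance layer: 'roadNear'")
  if (missing(protected)) stop("missing disturbance layer: 'protected'")
  if (missing(deforested)) stop("missing disturbance layer: 'deforested'")
  if (is.null(grid)) grid <- tempTrend@grid
  if (is.null(savannaBiome)) {
    savannaBiome <- matrix(FALSE, grid@nrow, grid@ncol)
  }
  new("DisturbanceStack",
    tempTrend = tempTrend, stability2050 = stability2050,
    droughtCounts = droughtCounts, roadNear = roadNear,
    protected = protected, deforested = deforested,
    savannaBiome = savannaBiome, grid = grid
  )
}

#' Transition-potential map
#'
#' @slot tp numeric matrix of index values (NA where excluded).
#' @slot category character matrix (\code{"low"}, \code{"moderate"},
#'   \code{"high"}, NA where excluded).
#' @slot areaFractions named fractions per category over the analysis
#'   mask (sum to 1), plus the cumulative moderate-or-high share in
#'   \code{moderateOrHigh}.
#' @slot config the [tpConfig()] used.
#' @slot grid a [GridSpec-class].
#' @export
setClass("TransitionPotentialMap",
  representation(
    tp = "matrix", category = "matrix", areaFractions = "numeric",
    moderateOrHigh = "numeric", config = "list", grid = "GridSpec"
  )
)

#' @rdname mapValues
#' @export
tpValues <- function(x) x@tp

setMethod("show", "TransitionPotentialMap", function(object) {
  f <- object@areaFractions
  cat("TransitionPotentialMap: ",
    sum(!is.na(object@tp)), " analysed pixels; ",
    paste(sprintf("%s %.1f%%", names(f), 100 * f), collapse = ", "),
    " (moderate-or-high ",
    sprintf("%.1f%%", 100 * object@moderateOrHigh), ")\n",
    sep = ""
  )
})

#' Rasterise road proximity
#'
#' Marks every pixel whose centre lies within \code{bufferKm}
#' (great-circle, boundary inclusive) of any road polyline. Each segment
#' is vertex-interpolated at \code{spacingKm} resolution and pixel
#' centres are compared against the densified vertices with spherical
#' (haversine) distances; the chord-sampling error at the 10-km buffer
#' boundary is a few metres, far below the pixel size. Planar
#' approximations are avoided because the grid is geographic.
#'
#' @param roads list of polylines, each a 2-column lon/lat vertex matrix;
#'   an empty list yields an all-FALSE mask.
#' @param grid a [GridSpec-class].
#' @param bufferKm buffer distance, default 10 km.
#' @param spacingKm segment densification step (default 0.5 km).
#' @return list with \code{near} (logical matrix) and \code{distanceKm}
#'   (numeric matrix, Inf when there are no roads).
#' @export
roadProximity <- function(roads, grid, bufferKm = 10, spacingKm = 0.5) {
  dist <- matrix(Inf, grid@nrow, grid@ncol)
  if (length(roads)) {
    pts <- cbind(as.vector(cellLon(grid)), as.vector(cellLat(grid)))
    d <- rep(Inf, nrow(pts))
    for (line in roads) {
      stopifnot(is.matrix(line), ncol(line) == 2L)
      dense <- densifyPolyline(line, spacingKm)
      for (k in seq_len(nrow(dense))) {
        d <- pmin(d, geosphere::distHaversine(dense[k, ], pts))
      }
    }
    dist <- cellsToMatrix(d / 1000, grid)
  }
  list(near = dist <= bufferKm, distanceKm = dist)
}

# linear vertex interpolation of a lon/lat polyline at ~spacingKm steps
densifyPolyline <- function(line, spacingKm) {
  if (nrow(line) == 1L) return(line)
  pieces <- lapply(seq_len(nrow(line) - 1L), function(k) {
    a <- line[k, ]; b <- line[k + 1L, ]
    lenKm <- geosphere::distHaversine(a, b) / 1000
    npts <- max(2L, ceiling(lenKm / spacingKm) + 1L)
    t <- seq(0, 1, length.out = npts)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  })
  do.call(rbind, pieces)
}

#' Compute the additive transition-potential index
#'
#' tp = tempSlopeFactor x (significant dry-season temperature slope, else
#' 0) + class score + droughtWeight x events + roadScore x [near road] +
#' governanceScore x [protected]. Pixels that are deforested, in the
#' savanna biome, or lack a stability class are excluded (NA). The result
#' is categorised with [categorizeTP()].
#'
#' @param stack a [DisturbanceStack-class].
#' @param cfg a [tpConfig()].
#' @return a [TransitionPotentialMap-class].
#' @examples
#' # a savanna-class pixel with 5 droughts near an unprotected road:
#' # 2 + 5*0.2 + 1 = 4; a protected forest pixel with none: -1
#' @export
computeTransitionPotential <- function(stack, cfg = tpConfig()) {
  slope <- stack@tempTrend@slope
  sig <- isSignificant(stack@tempTrend)
  slopeTerm <- ifelse(sig, slope, 0)

  cl <- stack@stability2050@classes
  scores <- cfg$classScores[classLabels]
  classTerm <- matrix(scores[cl + 1L], nrow(cl), ncol(cl))

  tp <- cfg$tempSlopeFactor * slopeTerm +
    classTerm +
    cfg$droughtWeight * stack@droughtCounts +
    cfg$roadScore * stack@roadNear +
    cfg$governanceScore * stack@protected
  tp[stack@deforested | stack@savannaBiome | is.na(cl)] <- NA_real_

  categorizeTP(tp, cfg, grid = stack@grid)
}

#' Categorise a transition-potential raster
#'
#' Default (\code{"text"}) rule: low tp <= 1, moderate 1 < tp <= 2,
#' high tp > 2. The \code{"figure"} rule (low < 0, moderate in [1, 2],
#' high > 2) is available as an alternative; its unlabelled [0, 1)
#' interval is mapped to low. Area fractions are computed over the
#' analysed (non-NA) pixels and always sum to 1.
#'
#' @param tp numeric matrix of index values (or a
#'   [TransitionPotentialMap-class] to re-categorise).
#' @param cfg a [tpConfig()] carrying the category rule.
#' @param grid a [GridSpec-class].
#' @return a [TransitionPotentialMap-class].
#' @export
categorizeTP <- function(tp, cfg = tpConfig(), grid) {
  if (is(tp, "TransitionPotentialMap")) {
    grid <- tp@grid
    tp <- tp@tp
  }
  cat_ <- matrix(NA_character_, nrow(tp), ncol(tp))
  ok <- !is.na(tp)
  if (cfg$categoryRule == "text") {
    cat_[ok & tp <= 1] <- "low"
    cat_[ok & tp > 1 & tp <= 2] <- "moderate"
    cat_[ok & tp > 2] <- "high"
  } else {
    cat_[ok & tp < 1] <- "low"
    cat_[ok & tp >= 1 & tp <= 2] <- "moderate"
    cat_[ok & tp > 2] <- "high"
  }
  n <- sum(ok)
  f <- vapply(c("low", "moderate", "high"),
              function(k) if (n) sum(cat_ == k, na.rm = TRUE) / n else
                NA_real_,
              numeric(1))
  new("TransitionPotentialMap",
    tp = tp, category = cat_, areaFractions = f,
    moderateOrHigh = unname(f["moderate"] + f["high"]),
    config = unclass(cfg), grid = grid
  )
}

#' Safe-boundary status report
#'
#' Compares driver values against the conservative safe boundaries:
#' annual rainfall 1800 mm yr-1 (safe above), MCWD -350 mm (safe above,
#' i.e. less negative), dry-season length 5 months (safe below) and
#' accumulated deforestation 10 % of the original forest area (safe
#' below). Boundaries are inclusive: a driver exactly on its boundary is
#' inside. Distances are signed in driver units, positive inside.
#'
#' @param map,mcwd,dsl,deforestedFraction scalar driver values; omit
#'   (NULL) any driver not assessed.
#' @return data.frame with columns \code{driver}, \code{value},
#'   \code{boundary}, \code{inside}, \code{distance}.
#' @examples
#' safeBoundaryReport(map = 2000, mcwd = -400, dsl = 4,
#'                    deforestedFraction = 0.10)
#' @export
safeBoundaryReport <- function(map = NULL, mcwd = NULL, dsl = NULL,
                               deforestedFraction = NULL) {
  rows <- list()
  if (!is.null(map)) {
    rows <- c(rows, list(data.frame(
      driver = "annual_rainfall", value = map, boundary = 1800,
      inside = map >= 1800, distance = map - 1800
    )))
  }
  if (!is.null(mcwd)) {
    rows <- c(rows, list(data.frame(
      driver = "mcwd", value = mcwd, boundary = -350,
      inside = mcwd >= -350, distance = mcwd - (-350)
    )))
  }
  if (!is.null(dsl)) {
    rows <- c(rows, list(data.frame(
      driver = "dry_season_length", value = dsl, boundary = 5,
      inside = dsl <= 5, distance = 5 - dsl
    )))
  }
  if (!is.null(deforestedFraction)) {
    rows <- c(rows, list(data.frame(
      driver = "deforestation", value = deforestedFraction,
      boundary = 0.10, inside = deforestedFraction <= 0.10,
      distance = 0.10 - deforestedFraction
    )))
  }
  if (!length(rows)) stop("no driver supplied")
  do.call(rbind, rows)
}
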