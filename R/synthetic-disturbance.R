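#' Synthetic disturbance configuration
#'
#' Parameters for the disturbance-layer generator: extreme-drought event
#' counts (0-5 per pixel), random-walk road polylines, a protection mask
#' (protected areas and Indigenous territories) and a deforestation mask.
#'
#' @param nRoads number of road polylines.
#' @param roadSteps vertices per road (random-walk length).
#' @param roadStepDeg step length of the random walk, degrees.
#' @param protectedFraction,deforestedFraction target areal fractions;
#'   their sum must not exceed 1 (the masks are disjoint).
#' @param droughtLambda mean of the (0-5 truncated) Poisson drought-count
#'   distribution.
#' @param roadBufferKm distance defining "near a road" (km).
#' @param seed integer RNG seed.
#' @return list of class \code{"DisturbanceConfig"}.
#' @export
disturbanceConfig <- function(nRoads = 5L, roadSteps = 25L,
                              roadStepDeg = 0.15,
                              protectedFraction = 0.3,
                              deforestedFraction = 0.1,
                              droughtLambda = 1.5,
                              roadBufferKm = 10,
                              seed = 1L) {
  stopifnot(
    protectedFraction >= 0, protectedFraction <= 1,
    deforestedFraction >= 0, deforestedFraction <= 1,
    droughtLambda >= 0, roadBufferKm > 0, nRoads >= 0
  )
  if (protectedFraction + deforestedFraction > 1) {
    stop("protectedFraction + deforestedFraction must not exceed 1")
  }
  cfg <- list(
    nRoads = as.integer(nRoads), roadSteps = as.integer(roadSteps),
    roadStepDeg = roadStepDeg,
    protectedFraction = protectedFraction,
    deforestedFraction = deforestedFraction,
    droughtLambda = droughtLambda, roadBufferKm = roadBufferKm,
    seed = as.integer(seed)
  )
  class(cfg) <- "DisturbanceConfig"
  cfg
}

# random-walk polyline inside the grid bounding box; only distance-to-road
# matters downstream, so geometry realism is not attempted
randomWalkRoad <- function(grid, steps, stepDeg) {
  lonRange <- grid@originLon + c(0, (grid@ncol - 1)) * grid@pixelSize
  latRange <- grid@originLat - c((grid@nrow - 1), 0) * grid@pixelSize
  lon <- numeric(steps); lat <- numeric(steps)
  lon[1] <- stats::runif(1, lonRange[1], lonRange[2])
  lat[1] <- stats::runif(1, latRange[1], latRange[2])
  heading <- stats::runif(1, 0, 2 * pi)
  for (k in seq_len(steps - 1L)) {
    heading <- heading + stats::rnorm(1, sd = 0.5)
    lon[k + 1] <- min(max(lon[k] + stepDeg * cos(heading), lonRange[1]),
                      lonRange[2])
    lat[k + 1] <- min(max(lat[k] + stepDeg * sin(heading), latRange[1]),
                      latRange[2])
  }
  cbind(lon = lon, lat = lat)
}

#' Generate synthetic disturbance layers
#'
#' Produces, on a shared grid: an integer drought-count raster (Poisson
#' with mean \code{droughtLambda}, capped at 5 events), \code{nRoads}
#' random-walk road polylines with the derived road-proximity mask,
#' and disjoint protection and deforestation masks hitting their target
#' areal fractions exactly (cells sampled at random).
#'
#' @param cfg a [disturbanceConfig()].
#' @param grid a [GridSpec-class].
#' @return list with \code{droughtCounts} (integer matrix),
#'   \code{roads} (list of lon/lat vertex matrices), \code{roadNear}
#'   (logical matrix), \code{roadDistanceKm} (numeric matrix),
#'   \code{protected} and \code{deforested} (logical matrices).
#' @export
simulateDisturbances <- function(cfg, grid) {
  set.seed(cfg$seed)
  n <- nCells(grid)

  counts <- pmin(stats::rpois(n, cfg$droughtLambda), 5L)
  droughtCounts <- cellsToMatrix(as.integer(counts), grid)

  roads <- lapply(seq_len(cfg$nRoads), function(i) {
    randomWalkRoad(grid, cfg$roadSteps, cfg$roadStepDeg)
  })
  prox <- roadProximity(roads, grid, bufferKm = cfg$roadBufferKm)

  nProt <- round(cfg$protectedFraction * n)
  nDef <- round(cfg$deforestedFraction * n)
  pick <- sample.int(n, nProt + nDef)
  protected <- logical(n); protected[pick[seq_len(nProt)]] <- TRUE
  deforested <- logical(n)
  if (nDef > 0) deforested[pick[nProt + seq_len(nDef)]] <- TRUE

  list(
    droughtCounts = droughtCounts,
    roads = roads,
    roadNear = prox$near,
    roadDistanceKm = prox$distanceKm,
    protected = cellsToMatrix(protected, grid),
    deforested = cellsToMatrix(deforested, grid)
  )
}
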