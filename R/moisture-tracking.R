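#' @include grid.R
NULL

#' Moisture-tracking configuration
#'
#' Parameters of the simplified single-layer Lagrangian moisture tracker:
#' 100 parcels are released per millimetre of evapotranspiration, parcel
#' coordinates advance in 0.1-h time steps through the wind field, and at
#' each step the fraction P * dt / TPW of a parcel's moisture rains out
#' at its current cell (P the local precipitation rate, TPW the local
#' precipitable water). A parcel is terminated once its remaining
#' moisture drops below \code{terminationFraction} of its initial load or
#' its age exceeds \code{maxAgeHours}; remaining moisture is booked as
#' residual. Parcels leaving the domain are booked as exited.
#'
#' @param parcelsPerMm parcels released per mm of evapotranspiration
#'   (default 100).
#' @param dtHours time step in hours (default 0.1).
#' @param maxAgeHours tracking horizon (default 720 h = 30 days).
#' @param terminationFraction stop threshold as a fraction of the initial
#'   parcel moisture, in (0, 1) (default 0.01).
#' @param hoursPerMonth conversion from monthly forcing to per-step rates
#'   (default 730).
#' @param seed integer seed for the uniform sub-cell release jitter.
#' @return list of class \code{"MoistureConfig"}.
#' @export
moistureConfig <- function(parcelsPerMm = 100, dtHours = 0.1,
                           maxAgeHours = 720, terminationFraction = 0.01,
                           hoursPerMonth = 730, seed = 1L) {
  stopifnot(
    parcelsPerMm >= 1, dtHours > 0, maxAgeHours > 0,
    terminationFraction > 0, terminationFraction < 1
  )
  structure(
    list(
      parcelsPerMm = parcelsPerMm, dtHours = dtHours,
      maxAgeHours = maxAgeHours,
      terminationFraction = terminationFraction,
      hoursPerMonth = hoursPerMonth, seed = as.integer(seed)
    ),
    class = "MoistureConfig"
  )
}

#' Gridded forcing for the moisture tracker
#'
#' Time-invariant (monthly climatological) forcing on one grid: zonal and
#' meridional wind (m s-1), evapotranspiration and precipitation
#' (mm month-1) and total precipitable water (mm). TPW must be positive
#' wherever precipitation is positive, otherwise the allocation fraction
#' is undefined.
#'
#' @slot u,v,evap,precip,tpw numeric matrices on \code{grid}.
#' @slot grid a [GridSpec-class].
#' @export
setClass("MoistureForcing",
  representation(
    u = "matrix", v = "matrix", evap = "matrix", precip = "matrix",
    tpw = "matrix", grid = "GridSpec"
  )
)

setValidity("MoistureForcing", function(object) {
  msg <- character()
  g <- object@grid
  for (nm in c("u", "v", "evap", "precip", "tpw")) {
    m <- slot(object, nm)
    if (nrow(m) != g@nrow || ncol(m) != g@ncol)
      msg <- c(msg, paste0("field '", nm, "' does not match the grid"))
    if (any(!is.finite(m))) msg <- c(msg, paste0("field '", nm,
                                                 "' must be finite"))
  }
  if (any(slot(object, "evap") < 0)) msg <- c(msg, "evap must be >= 0")
  if (any(slot(object, "precip") < 0)) msg <- c(msg, "precip must be >= 0")
  if (any(object@precip > 0 & object@tpw <= 0))
    msg <- c(msg, "tpw must be > 0 wherever precip > 0")
  if (length(msg)) msg else TRUE
})

#' Construct moisture-tracking forcing
#'
#' Scalars are recycled to full fields, so
#' \code{moistureForcing(grid, u = 5, v = 0, evap = 0.1, precip = 150,
#' tpw = 30)} builds a uniform forcing bundle.
#'
#' @param grid a [GridSpec-class].
#' @param u,v wind components (m s-1).
#' @param evap evapotranspiration (mm month-1).
#' @param precip precipitation (mm month-1).
#' @param tpw total precipitable water (mm).
#' @return a [MoistureForcing-class].
#' @export
moistureForcing <- function(grid, u, v, evap, precip, tpw) {
  full <- function(x) {
    if (is.matrix(x)) x else matrix(x, grid@nrow, grid@ncol)
  }
  new("MoistureForcing",
    u = full(u), v = full(v), evap = full(evap),
    precip = full(precip), tpw = full(tpw), grid = grid
  )
}

#' Release moisture parcels from the evapotranspiration field
#'
#' Each cell releases \code{round(evap * parcelsPerMm)} parcels, jittered
#' uniformly within the cell, each carrying an equal share of the cell's
#' evapotranspiration, so total released moisture equals total
#' evapotranspiration exactly. Cells with zero evapotranspiration release
#' nothing.
#'
#' @param forcing a [MoistureForcing-class].
#' @param cfg a [moistureConfig()].
#' @return data.frame with one row per parcel: \code{lon}, \code{lat},
#'   \code{moisture}, \code{initial}, \code{age}, \code{sourceCell}.
#' @export
releaseParcels <- function(forcing, cfg = moistureConfig()) {
  e <- forcing@evap
  if (any(e < 0)) stop("negative evapotranspiration")
  g <- forcing@grid
  counts <- round(as.vector(e) * cfg$parcelsPerMm)
  idx <- which(counts > 0)
  if (!length(idx)) {
    return(data.frame(lon = numeric(), lat = numeric(),
                      moisture = numeric(), initial = numeric(),
                      age = numeric(), sourceCell = integer()))
  }
  set.seed(cfg$seed)
  cellIdx <- rep(idx, counts[idx])
  n <- length(cellIdx)
  lon <- as.vector(cellLon(g))[cellIdx] +
    (stats::runif(n) - 0.5) * g@pixelSize
  lat <- as.vector(cellLat(g))[cellIdx] +
    (stats::runif(n) - 0.5) * g@pixelSize
  moist <- rep(as.vector(e)[idx] / counts[idx], counts[idx])
  data.frame(lon = lon, lat = lat, moisture = moist, initial = moist,
             age = 0, sourceCell = cellIdx)
}

# metres per degree; meridian-mean Earth radius convention
M_PER_DEG <- 111195

#' Advect parcel coordinates one time step
#'
#' Displacement is wind x dt, converted to degrees at each parcel's
#' latitude (zonal metres shrink with cos(lat)).
#'
#' @param lon,lat parcel coordinates (degrees).
#' @param u,v wind at the parcels (m s-1).
#' @param dtHours time step (hours).
#' @return list with updated \code{lon}, \code{lat}.
#' @examples
#' advectParcels(0, 0, u = 10, v = 0, dtHours = 0.1)  # 3.6 km east
#' @export
advectParcels <- function(lon, lat, u, v, dtHours) {
  dtSec <- dtHours * 3600
  lon2 <- lon + u * dtSec / (M_PER_DEG * cos(lat * pi / 180))
  lat2 <- lat + v * dtSec / M_PER_DEG
  list(lon = lon2, lat = lat2)
}

# bilinear interpolation of a grid field at parcel positions; positions
# outside the pixel-centre hull clamp to the edge (the domain-exit test
# happens separately)
bilinearAt <- function(field, grid, lon, lat) {
  x <- (lon - grid@originLon) / grid@pixelSize + 1
  y <- (grid@originLat - lat) / grid@pixelSize + 1
  x <- pmin(pmax(x, 1), grid@ncol)
  y <- pmin(pmax(y, 1), grid@nrow)
  x0 <- pmin(floor(x), grid@ncol - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(y), grid@nrow - 1L); y1 <- y0 + 1
  if (grid@ncol == 1L) { x0 <- x1 <- rep(1, length(x)); }
  if (grid@nrow == 1L) { y0 <- y1 <- rep(1, length(y)); }
  fx <- x - x0; fy <- y - y0
  f00 <- field[cbind(y0, x0)]; f01 <- field[cbind(y0, x1)]
  f10 <- field[cbind(y1, x0)]; f11 <- field[cbind(y1, x1)]
  f00 * (1 - fx) * (1 - fy) + f01 * fx * (1 - fy) +
    f10 * (1 - fx) * fy + f11 * fx * fy
}

# nearest-cell index (column-major) of parcel positions; NA outside the
# domain (beyond half a pixel from the outermost centres)
nearestCell <- function(grid, lon, lat) {
  col <- round((lon - grid@originLon) / grid@pixelSize) + 1
  row <- round((grid@originLat - lat) / grid@pixelSize) + 1
  out <- col < 0.5 | col > grid@ncol + 0.5 | row < 0.5 |
    row > grid@nrow + 0.5
  col <- pmin(pmax(col, 1), grid@ncol)
  row <- pmin(pmax(row, 1), grid@nrow)
  idx <- (col - 1) * grid@nrow + row
  idx[out] <- NA_integer_
  as.integer(idx)
}

#' Per-step precipitation allocation fraction
#'
#' fraction = min(1, P * dt / TPW) with P the monthly precipitation
#' scaled to the time step.
#'
#' @param precip precipitation (mm month-1) at the parcels.
#' @param tpw precipitable water (mm) at the parcels.
#' @param cfg a [moistureConfig()].
#' @return allocation fractions in [0, 1].
#' @export
allocationFraction <- function(precip, tpw, cfg = moistureConfig()) {
  rate <- precip * cfg$dtHours / cfg$hoursPerMonth
  frac <- ifelse(precip > 0, pmin(1, rate / tpw), 0)
  frac
}

#' Run the Lagrangian moisture-tracking simulation
#'
#' Releases parcels from the evapotranspiration field, advects them
#' through the wind field in \code{dtHours} steps, rains out the
#' P * dt / TPW fraction of each parcel's moisture at every step, and
#' keeps a complete ledger: released = allocated + exited + residual
#' holds to numerical round-off on every run.
#'
#' @param forcing a [MoistureForcing-class].
#' @param cfg a [moistureConfig()].
#' @param regions optional integer matrix of region ids on the grid (NA =
#'   untracked), or a list of disjoint logical masks; enables
#'   source-region bookkeeping for [aggregateFlows()].
#' @return list of class \code{"MoistureLedger"}: \code{totals}
#'   (released/allocated/exited/residual), \code{allocationByCell}
#'   (matrix, mm), \code{flowByRegion} (source region x target cell
#'   matrix, when regions given), \code{regions}, \code{nParcels},
#'   \code{steps}, \code{grid}.
#' @export
trackMoisture <- function(forcing, cfg = moistureConfig(),
                          regions = NULL) {
  g <- forcing@grid
  regionIds <- NULL
  if (!is.null(regions)) regionIds <- normalizeRegions(regions, g)

  parcels <- releaseParcels(forcing, cfg)
  released <- sum(parcels$moisture)
  n <- nrow(parcels)
  lon <- parcels$lon; lat <- parcels$lat
  moist <- parcels$moisture; initial <- parcels$initial
  nTrue <- if (!is.null(regionIds)) max(c(regionIds, 1L), na.rm = TRUE)
           else 1L
  srcRegion <- if (!is.null(regionIds)) {
    regionIds[parcels$sourceCell]
  } else rep(1L, n)
  # parcels released from untracked cells book into an internal extra row
  srcRegion[is.na(srcRegion)] <- nTrue + 1L
  nRegions <- nTrue + 1L

  nC <- nCells(g)
  flowVec <- numeric(nRegions * nC)     # [(region-1)*nC + cell]
  exited <- 0
  residual <- 0
  active <- rep(TRUE, n)
  maxSteps <- ceiling(cfg$maxAgeHours / cfg$dtHours)
  uV <- forcing@u; vV <- forcing@v
  pV <- forcing@precip; tV <- forcing@tpw

  step <- 0L
  while (any(active) && step < maxSteps) {
    step <- step + 1L
    ia <- which(active)
    uu <- bilinearAt(uV, g, lon[ia], lat[ia])
    vv <- bilinearAt(vV, g, lon[ia], lat[ia])
    newPos <- advectParcels(lon[ia], lat[ia], uu, vv, cfg$dtHours)
    lon[ia] <- newPos$lon; lat[ia] <- newPos$lat

    cell <- nearestCell(g, lon[ia], lat[ia])
    gone <- is.na(cell)
    if (any(gone)) {
      exited <- exited + sum(moist[ia[gone]])
      moist[ia[gone]] <- 0
      active[ia[gone]] <- FALSE
    }
    stay <- ia[!gone]; cellS <- cell[!gone]
    if (length(stay)) {
      frac <- allocationFraction(pV[cellS], tV[cellS], cfg)
      dm <- moist[stay] * frac
      take <- dm > 0
      if (any(take)) {
        key <- (srcRegion[stay][take] - 1L) * nC + cellS[take]
        agg <- rowsum(dm[take], key)
        k <- as.integer(rownames(agg))
        flowVec[k] <- flowVec[k] + agg[, 1]
      }
      moist[stay] <- moist[stay] - dm
      done <- moist[stay] < cfg$terminationFraction * initial[stay]
      if (any(done)) {
        residual <- residual + sum(moist[stay[done]])
        moist[stay[done]] <- 0
        active[stay[done]] <- FALSE
      }
    }
  }
  if (any(active)) {                      # age limit reached
    residual <- residual + sum(moist[active])
    moist[active] <- 0
    active[] <- FALSE
  }
  flow <- t(matrix(flowVec, nC, nRegions))   # source region x target cell
  alloc <- colSums(flow)
  structure(
    list(
      totals = c(released = released, allocated = sum(alloc),
                 exited = exited, residual = residual),
      allocationByCell = cellsToMatrix(alloc, g),
      flowByRegion = flow,
      regions = regionIds, nRegions = nTrue,
      nParcels = n, steps = step, grid = g
    ),
    class = "MoistureLedger"
  )
}

# regions as integer matrix or list of logical masks -> integer vector
# per cell (NA outside); overlapping masks are an error
normalizeRegions <- function(regions, grid) {
  if (is.list(regions)) {
    ids <- rep(NA_integer_, nCells(grid))
    for (k in seq_along(regions)) {
      m <- as.vector(regions[[k]])
      if (any(!is.na(ids[m]))) stop("overlapping regions")
      ids[m] <- k
    }
    ids
  } else {
    as.integer(as.vector(regions))
  }
}

#' Country-to-country moisture flow matrix
#'
#' Aggregates a tracking ledger into source-region x target-region annual
#' flows, with each target's rainfall fraction by source computed on the
#' tracked (allocated) moisture. A reporting filter marks fractions above
#' the display threshold (10 % by convention).
#'
#' @slot flows numeric source x target matrix (mm, tracked moisture).
#' @slot fractions per-target share of tracked rainfall by source
#'   (columns sum to 1 where any moisture arrived).
#' @slot reported logical matrix, TRUE where the fraction exceeds the
#'   reporting threshold.
#' @slot regionNames character labels.
#' @export
setClass("FlowMatrix",
  representation(
    flows = "matrix", fractions = "matrix", reported = "matrix",
    regionNames = "character"
  )
)

setValidity("FlowMatrix", function(object) {
  msg <- character()
  if (any(object@flows < 0)) msg <- c(msg, "flows must be >= 0")
  cs <- colSums(object@fractions)
  if (any(cs > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "per-target fractions must sum to <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FlowMatrix", function(object) {
  cat("FlowMatrix: ", nrow(object@flows), " regions, total tracked flow ",
    sprintf("%.4g", sum(object@flows)), " mm; ",
    sum(object@reported), " flows above the reporting threshold\n",
    sep = ""
  )
})

#' Aggregate a tracking ledger into a flow matrix
#'
#' @param ledger a \code{"MoistureLedger"} from [trackMoisture()] run
#'   with \code{regions}.
#' @param regionNames optional labels (default R1, R2, ...).
#' @param reportingThreshold fractions strictly above this are flagged
#'   for display (default 0.1).
#' @return a [FlowMatrix-class].
#' @export
aggregateFlows <- function(ledger, regionNames = NULL,
                           reportingThreshold = 0.1) {
  if (is.null(ledger$regions)) stop("ledger was run without regions")
  ids <- ledger$regions
  nR <- ledger$nRegions
  flows <- matrix(0, nR, nR)
  for (t in seq_len(nR)) {
    cols <- which(!is.na(ids) & ids == t)
    if (length(cols)) {
      # drop the internal untracked-source row, if present
      flows[, t] <- rowSums(
        ledger$flowByRegion[seq_len(nR), cols, drop = FALSE]
      )
    }
  }
  if (is.null(regionNames)) regionNames <- paste0("R", seq_len(nR))
  dimnames(flows) <- list(source = regionNames, target = regionNames)
  tot <- colSums(flows)
  fractions <- sweep(flows, 2, ifelse(tot > 0, tot, NA), "/")
  fractions[, tot == 0] <- 0
  new("FlowMatrix",
    flows = flows, fractions = fractions,
    reported = fractions > reportingThreshold,
    regionNames = regionNames
  )
}
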