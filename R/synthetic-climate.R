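#' Synthetic monthly climate configuration
#'
#' Parameters of the synthetic precipitation/temperature cube generator.
#' Each pixel's monthly series is climatology + a linear year trend +
#' Gaussian noise (precipitation truncated at zero). Injected trends are
#' recorded as ground truth so downstream trend fits can be validated.
#'
#' The default monthly climatology is an Amazon-like seasonal cycle
#' (wet austral summer, July-October dry season; annual total about
#' 2260 mm). The default temperature trend of 0.027 deg C yr-1 matches
#' the observed regional dry-season warming of 0.27 deg C per decade.
#'
#' @param years integer calendar years, default 1981:2020.
#' @param monthlyClimatology 12 monthly precipitation normals (mm).
#' @param precipTrend trend of the annual total, mm yr-1 per year
#'   (distributed evenly over months).
#' @param tempBase mean temperature (deg C) in the first year.
#' @param tempTrend deg C per year.
#' @param tempSeasonalAmp amplitude (deg C) of a sinusoidal seasonal
#'   temperature cycle peaking in the dry season.
#' @param noiseSdPrecip,noiseSdTemp Gaussian noise sd (mm month-1, deg C).
#' @param seed integer RNG seed.
#' @return list of class \code{"ClimateConfig"}.
#' @export
climateConfig <- function(years = 1981:2020,
                          monthlyClimatology = c(300, 280, 300, 260, 180,
                                                 100, 60, 50, 80, 150,
                                                 220, 280),
                          precipTrend = 0,
                          tempBase = 25, tempTrend = 0.027,
                          tempSeasonalAmp = 1,
                          noiseSdPrecip = 15, noiseSdTemp = 0.3,
                          seed = 1L) {
  stopifnot(
    length(years) >= 3L,                       # regression needs >= 3 points
    length(monthlyClimatology) == 12L,
    noiseSdPrecip >= 0, noiseSdTemp >= 0
  )
  if (any(monthlyClimatology < 0)) stop("negative climatology")
  cfg <- list(
    years = as.integer(years),
    monthlyClimatology = monthlyClimatology,
    precipTrend = precipTrend,
    tempBase = tempBase, tempTrend = tempTrend,
    tempSeasonalAmp = tempSeasonalAmp,
    noiseSdPrecip = noiseSdPrecip, noiseSdTemp = noiseSdTemp,
    seed = as.integer(seed)
  )
  class(cfg) <- "ClimateConfig"
  cfg
}

#' Generate synthetic monthly climate cubes
#'
#' Builds a precipitation and a temperature [ClimateCube-class] on
#' \code{grid}. Optionally the precipitation climatology is rescaled per
#' pixel so that the pixel's expected mean annual precipitation matches a
#' target MAP field (keeping the seasonal shape), which couples the cubes
#' to a synthetic biome.
#'
#' @param cfg a [climateConfig()].
#' @param grid a [GridSpec-class].
#' @param scaleToMAP optional [MetricMap-class] with metric \code{"MAP"};
#'   per-pixel climatology is multiplied by MAP / sum(climatology).
#' @return list with \code{precip} and \code{temp} cubes and \code{truth}
#'   (the injected trends).
#' @examples
#' g <- gridSpec(5, 5)
#' cl <- simulateClimate(climateConfig(noiseSdPrecip = 0, noiseSdTemp = 0), g)
#' dim(cubeValues(cl$precip))
#' @export
simulateClimate <- function(cfg, grid, scaleToMAP = NULL) {
  set.seed(cfg$seed)
  n <- nCells(grid)
  ny <- length(cfg$years)
  yIdx <- cfg$years - cfg$years[1]

  scale <- rep(1, n)
  if (!is.null(scaleToMAP)) {
    stopifnot(metricName(scaleToMAP) == "MAP")
    assertSameGrid(grid, gridOf(scaleToMAP))
    scale <- as.vector(mapValues(scaleToMAP)) / sum(cfg$monthlyClimatology)
  }

  precip <- array(0, dim = c(n, ny, 12))
  temp <- array(0, dim = c(n, ny, 12))
  seasonal <- cfg$tempSeasonalAmp * cos(2 * pi * ((1:12) - 8) / 12)
  for (m in 1:12) {
    base <- outer(scale * cfg$monthlyClimatology[m],
                  1 + numeric(ny)) +
      matrix(rep(cfg$precipTrend * yIdx / 12, each = n), nrow = n)
    noise <- if (cfg$noiseSdPrecip > 0) {
      matrix(stats::rnorm(n * ny, sd = cfg$noiseSdPrecip), nrow = n)
    } else 0
    precip[, , m] <- pmax(0, base + noise)

    tbase <- cfg$tempBase + seasonal[m] +
      matrix(rep(cfg$tempTrend * yIdx, each = n), nrow = n)
    tnoise <- if (cfg$noiseSdTemp > 0) {
      matrix(stats::rnorm(n * ny, sd = cfg$noiseSdTemp), nrow = n)
    } else 0
    temp[, , m] <- tbase + tnoise
  }

  list(
    precip = climateCube(precip, cfg$years, "precip", grid),
    temp = climateCube(temp, cfg$years, "temp", grid),
    truth = list(precipTrend = cfg$precipTrend, tempTrend = cfg$tempTrend)
  )
}
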