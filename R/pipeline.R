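#' End-to-end analysis pipeline on synthetic data
#'
#' Runs the full chain in dependency order on one shared grid: simulate
#' the biome, climate cubes and disturbance layers; compute MAP, MCWD,
#' DSL and the dry-season temperature series; fit per-pixel rainfall and
#' temperature trends; build the MAP stability landscape and extract
#' thresholds; classify current and 2050 stability; compute and
#' categorise the transition-potential index; and assemble a
#' safe-boundary report from biome-mean driver values. Everything is
#' deterministic under \code{seed}.
#'
#' @param seed integer master seed, propagated to every generator.
#' @param biome a [biomeConfig()] (its seed is overridden by \code{seed}).
#' @param climate a [climateConfig()] (seed likewise).
#' @param disturbance a [disturbanceConfig()] (seed likewise).
#' @param tp a [tpConfig()].
#' @param useRecoveredThresholds classify with the thresholds recovered
#'   by the potential analysis (default) rather than the canonical
#'   1000/1800 mm.
#' @param outDir optional directory; when given, the report (JSON), the
#'   exact configuration and seed (JSON), the class/tp rasters (.asc) and
#'   the roads (GeoJSON) are written there.
#' @return list of class \code{"PipelineReport"} with sections
#'   \code{thresholds}, \code{classFractions}, \code{transitions},
#'   \code{tpFractions}, \code{safeBoundary}, \code{seed}, and the
#'   intermediate objects in \code{objects}.
#' @export
runPipeline <- function(seed = 1L,
                        biome = biomeConfig("map"),
                        climate = climateConfig(),
                        disturbance = disturbanceConfig(),
                        tp = tpConfig(),
                        useRecoveredThresholds = TRUE,
                        outDir = NULL) {
  biome$seed <- as.integer(seed)
  climate$seed <- as.integer(seed) + 1L
  disturbance$seed <- as.integer(seed) + 2L

  bio <- simulateBiome(biome)
  grid <- gridOf(bio$metric)
  cl <- simulateClimate(climate, grid, scaleToMAP = bio$metric)

  mapNow <- computeMAP(cl$precip)
  mcwdMap <- computeMCWD(cl$precip)
  dslMap <- computeDSL(cl$precip)

  landscape <- buildStabilityLandscape(bio$treeCover, bio$metric,
                                       window = windowSpec("map"))
  th <- extractThresholds(landscape)
  lower <- if (useRecoveredThresholds && th$detected) th$lowerCritical
           else 1000
  upper <- if (useRecoveredThresholds && th$detected) th$upperCritical
           else 1800

  rainTrend <- fitTrendMap(annualTotals(cl$precip), cubeYears(cl$precip),
                           grid, units = "mm yr-1")
  tempTrend <- fitTrendMap(
    drySeasonTemperature(cl$temp), cubeYears(cl$temp), grid,
    units = "deg C"
  )

  classesNow <- classifyStability(mapNow, lower, upper)
  proj <- projectStability2050(mapNow, rainTrend, lower, upper)

  dist <- simulateDisturbances(disturbance, grid)
  mcwdYearly <- computeMCWD(cl$precip, perYear = TRUE)
  droughtCounts <- cellsToMatrix(
    detectDroughtEvents(mcwdYearly, cubeYears(cl$precip)), grid
  )
  stack <- disturbanceStack(
    tempTrend = tempTrend, stability2050 = proj$classMap2050,
    droughtCounts = droughtCounts, roadNear = dist$roadNear,
    protected = dist$protected, deforested = dist$deforested
  )
  tpMap <- computeTransitionPotential(stack, tp)

  fin <- function(m) mean(m[is.finite(m)])
  safe <- safeBoundaryReport(
    map = fin(mapValues(mapNow)),
    mcwd = fin(mapValues(mcwdMap)),
    dsl = fin(mapValues(dslMap)),
    deforestedFraction = mean(dist$deforested)
  )

  report <- list(
    seed = as.integer(seed),
    thresholds = th[c("lowerCritical", "upperCritical", "bistableRange",
                      "detected")],
    classFractions = as.list(classFractions(classesNow)),
    transitions = proj$transitions,
    tpFractions = c(as.list(tpMap@areaFractions),
                    moderateOrHigh = tpMap@moderateOrHigh),
    safeBoundary = safe,
    objects = list(
      biome = bio, climate = cl, landscape = landscape,
      classesNow = classesNow, projection = proj, stack = stack,
      tpMap = tpMap, mapNow = mapNow, mcwd = mcwdMap, dsl = dslMap
    )
  )
  class(report) <- "PipelineReport"

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    cfgOut <- list(
      seed = as.integer(seed), biome = unclass(biome),
      climate = unclass(climate), disturbance = unclass(disturbance),
      tp = unclass(tp)
    )
    jsonlite::write_json(cfgOut, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    slim <- report[c("seed", "thresholds", "classFractions",
                     "tpFractions")]
    slim$transitions <- report$transitions
    slim$safeBoundary <- report$safeBoundary
    jsonlite::write_json(slim, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    writeAsciiGrid(tpMap@tp, grid, file.path(outDir, "tp.asc"))
    writeAsciiGrid(
      matrix(as.numeric(proj$classMap2050@classes), grid@nrow),
      grid, file.path(outDir, "classes2050.asc")
    )
    writeRoadsGeoJSON(dist$roads, file.path(outDir, "roads.geojson"))
  }
  report
}
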