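test_that("generators are bit-identical under a fixed seed", {
  cfgB <- biomeConfig("map", gridShape = c(30L, 40L), seed = 11L)
  b1 <- simulateBiome(cfgB)
  b2 <- simulateBiome(cfgB)
  expect_identical(mapValues(b1$treeCover), mapValues(b2$treeCover))
  expect_identical(mapValues(b1$metric), mapValues(b2$metric))

  g <- tinyGrid()
  cfgC <- climateConfig(years = 2001:2010, seed = 5L)
  c1 <- simulateClimate(cfgC, g)
  c2 <- simulateClimate(cfgC, g)
  expect_identical(cubeValues(c1$precip), cubeValues(c2$precip))

  cfgD <- disturbanceConfig(seed = 9L)
  g2 <- gridSpec(20, 20, pixelSize = 0.1)
  d1 <- simulateDisturbances(cfgD, g2)
  d2 <- simulateDisturbances(cfgD, g2)
  expect_identical(d1$droughtCounts, d2$droughtCounts)
  expect_identical(d1$roads, d2$roads)
  expect_identical(d1$protected, d2$protected)
})

test_that("tree cover follows the conditional mixture construction", {
  # weight 1 forces the forest component everywhere in the bistable band
  cfg <- biomeConfig("map", gridShape = c(20L, 50L),
                     metricRange = c(1350, 1450),
                     bistableForestWeight = 1, seed = 2L)
  tc <- mapValues(simulateTreeCover(cfg, simulateMetricField(cfg)))
  expect_true(all(abs(tc - cfg$forestModeMean) <= 4 * cfg$forestModeSd))

  # below the lower threshold: savanna mode only, within +/- 4 sd
  cfg2 <- biomeConfig("map", gridShape = c(20L, 50L), seed = 3L)
  g <- gridSpec(20, 50)
  metric <- metricMap(matrix(500, 20, 50), "MAP", g)
  tc2 <- mapValues(simulateTreeCover(cfg2, metric))
  expect_true(all(tc2 <= cfg2$savannaModeMean + 4 * cfg2$savannaModeSd))
  expect_true(all(tc2 >= 0))

  # all values clipped into the physical range
  cfg3 <- biomeConfig("map", seed = 4L, gridShape = c(50L, 100L))
  b <- simulateBiome(cfg3)
  expect_true(all(mapValues(b$treeCover) >= 0 &
                    mapValues(b$treeCover) <= 100))
})

test_that("tree cover inside the bistable band is bimodal, outside unimodal", {
  b <- simulateBiome(biomeConfig("map", seed = 6L))
  tc <- as.vector(mapValues(b$treeCover))
  m <- as.vector(mapValues(b$metric))

  # inside the band both a low- and a high-cover state exist, with an
  # antimode between them
  inBand <- tc[m > 1100 & m < 1700]
  kd <- kdeDensity(inBand)
  eq <- findModes(kd$density, kd$grid)
  expect_true(any(eq$stable$position < 50))
  expect_true(any(eq$stable$position >= 50))
  expect_gte(nrow(eq$unstable), 1L)

  # the dry tail holds no high-cover state, the wet tail no low-cover
  # state (boundary clipping may add a spike at 0 or 100 inside a state)
  dry <- tc[m < 900]
  kdD <- kdeDensity(dry)
  expect_false(any(findModes(kdD$density, kdD$grid)$stable$position >= 50))
  wet <- tc[m > 1900]
  kdW <- kdeDensity(wet)
  expect_false(any(findModes(kdW$density, kdW$grid)$stable$position < 50))
})

test_that("degenerate biome configurations are rejected", {
  cfg <- biomeConfig("map", gridShape = c(10L, 10L),
                     metricRange = c(2000, 3000))
  # thresholds (1000, 1800) entirely below the metric range
  metric <- simulateMetricField(cfg)
  expect_error(simulateTreeCover(cfg, metric), "bistable zone")
  expect_error(biomeConfig("map", lowerThreshold = 1800,
                           upperThreshold = 1000))
})

test_that("climate generator injects recoverable trends", {
  g <- tinyGrid()
  # noise-free warming at 0.027 deg C / yr reads back as 0.27 / decade
  cl <- simulateClimate(
    climateConfig(tempTrend = 0.027, noiseSdTemp = 0, noiseSdPrecip = 0),
    g
  )
  series <- drySeasonTemperature(cl$temp)[1, ]
  fit <- fitTrend(series, cubeYears(cl$temp))
  expect_equal(fit$slope * 10, 0.27, tolerance = 1e-10)

  # no trend, no noise: every annual total identical
  cl0 <- simulateClimate(
    climateConfig(precipTrend = 0, noiseSdPrecip = 0, noiseSdTemp = 0), g
  )
  tot <- annualTotals(cl0$precip)
  expect_equal(max(tot) - min(tot), 0)

  # noisy series: distribution of fitted slopes centred on the injected one
  g1 <- gridSpec(1, 1)
  slopes <- vapply(1:200, function(s) {
    cl <- simulateClimate(
      climateConfig(precipTrend = 5, noiseSdPrecip = 30, seed = s), g1
    )
    fitTrend(annualTotals(cl$precip)[1, ], cubeYears(cl$precip))$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 5), 4 * se)
})

test_that("climate generator rejects invalid configurations", {
  expect_error(climateConfig(years = 2001:2002))       # < 3 years
  expect_error(climateConfig(monthlyClimatology = c(rep(100, 11), -5)),
               "negative climatology")
})

test_that("disturbance layers hit their targets", {
  g <- gridSpec(100, 100, pixelSize = 0.05)
  cfg <- disturbanceConfig(protectedFraction = 0.3,
                           deforestedFraction = 0.1,
                           droughtLambda = 1.5, seed = 21L)
  d <- simulateDisturbances(cfg, g)

  expect_lt(abs(mean(d$protected) - 0.3), 0.02)
  expect_lt(abs(mean(d$deforested) - 0.1), 0.02)
  expect_false(any(d$protected & d$deforested))
  expect_true(all(d$droughtCounts %in% 0:5))

  # truncated-Poisson oracle for the drought-count mean
  lam <- 1.5
  oracleMean <- sum(0:4 * dpois(0:4, lam)) + 5 * ppois(4, lam,
                                                       lower.tail = FALSE)
  se <- sqrt(lam / nCells(g))  # conservative
  expect_lt(abs(mean(d$droughtCounts) - oracleMean), 5 * se)

  # degenerate settings
  d0 <- simulateDisturbances(
    disturbanceConfig(nRoads = 0L, protectedFraction = 0, seed = 1L),
    gridSpec(20, 20, pixelSize = 0.1)
  )
  expect_false(any(d0$protected))
  expect_false(any(d0$roadNear))
  expect_true(all(is.infinite(d0$roadDistanceKm)))
  expect_error(disturbanceConfig(protectedFraction = 0.7,
                                 deforestedFraction = 0.5))
})

test_that("moisture forcing validates physical consistency", {
  g <- tinyGrid()
  expect_error(moistureForcing(g, u = 1, v = 0, evap = 1, precip = 100,
                               tpw = 0))
  # tpw can be zero where it never rains
  f <- moistureForcing(g, u = 1, v = 0, evap = 0, precip = 0, tpw = 0)
  expect_s4_class(f, "MoistureForcing")
  expect_identical(nrow(releaseParcels(f)), 0L)
})
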