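# shared fixtures: everything is generated in code at test time

tinyGrid <- function(nr = 4, nc = 5, px = 0.05) {
  gridSpec(nr, nc, originLon = -70, originLat = 0, pixelSize = px)
}

# constant-precipitation cube: mm per month, every cell and year
constantPrecipCube <- function(mm, grid = tinyGrid(), years = 2001:2005) {
  climateCube(array(mm, c(nCells(grid), length(years), 12)),
              years, "precip", grid)
}

constantTempCube <- function(degC, grid = tinyGrid(), years = 2001:2005) {
  climateCube(array(degC, c(nCells(grid), length(years), 12)),
              years, "temp", grid)
}

# cube with explicit per-month values (12-vector), same for all cells/years
monthlyPrecipCube <- function(months, grid = tinyGrid(1, 1),
                              years = 2001:2003) {
  v <- array(0, c(nCells(grid), length(years), 12))
  for (m in 1:12) v[, , m] <- months[m]
  climateCube(v, years, "precip", grid)
}

# small biome for fast landscape tests (2e4 pixels)
smallBiome <- function(variable = "map", seed = 1L) {
  simulateBiome(biomeConfig(variable, gridShape = c(100L, 200L),
                            seed = seed))
}

# brute-force Gaussian-sum KDE oracle: double loop, independent of the
# package's evaluation path
kdeOracle <- function(x, grid, h) {
  vapply(grid, function(g) {
    s <- 0
    for (xi in x) s <- s + exp(-0.5 * ((g - xi) / h)^2)
    s / (length(x) * h * sqrt(2 * pi))
  }, numeric(1))
}

# closed-form OLS oracle via the normal equations
olsOracle <- function(y, x) {
  n <- length(y)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  res <- y - intercept - slope * x
  se <- sqrt(sum(res^2) / (n - 2) / (sxx - sx^2 / n))
  tval <- slope / se
  list(slope = slope, intercept = intercept,
       pValue = 2 * pt(-abs(tval), df = n - 2))
}

# one-pixel disturbance stack with a prescribed layer combination
onePixelStack <- function(classCode, droughts, roadNear, protected,
                          tempSlope = 0, significant = FALSE) {
  g <- gridSpec(1, 1)
  p <- if (significant) 0.01 else 0.9
  tr <- new("TrendMap",
    slope = matrix(tempSlope), intercept = matrix(0),
    pValue = matrix(p), alpha = 0.1, units = "deg C", grid = g
  )
  cls <- new("StabilityClassMap",
    classes = matrix(as.integer(classCode)), lower = 1000, upper = 1800,
    epoch = "2050", grid = g
  )
  disturbanceStack(
    tempTrend = tr, stability2050 = cls,
    droughtCounts = matrix(as.integer(droughts)),
    roadNear = matrix(roadNear), protected = matrix(protected),
    deforested = matrix(FALSE)
  )
}

# vector -> grid matrix (mirrors the package's raster layout)
cellsToMatrixForTest <- function(v, grid) {
  matrix(v, nrow = grid@nrow, ncol = grid@ncol)
}
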