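test_that("Silverman bandwidth and KDE basics", {
  x <- rnorm(500, 50, 10)
  expect_equal(silvermanBandwidth(x), 1.06 * sd(x) * 500^(-0.2))
  expect_error(silvermanBandwidth(1))
  expect_error(silvermanBandwidth(rep(3, 10)))
  expect_error(kdeDensity(rnorm(5)), "below nMin")

  # symmetric sample gives a symmetric density
  xs <- 50 + c(-20, -10, -5, 5, 10, 20)
  kd <- kdeDensity(rep(xs, 30), nMin = 10L)
  expect_equal(kd$density, rev(kd$density), tolerance = 1e-10)

  # near-unit integral when the mass sits well inside the grid
  set.seed(1)
  kd2 <- kdeDensity(rnorm(2000, 50, 5))
  integral <- sum((kd2$density[-1] + kd2$density[-length(kd2$density)]) /
                    2 * diff(kd2$grid))
  expect_lt(abs(integral - 1), 1e-3)
  expect_true(all(kd2$density >= 0))
})

test_that("KDE equals the brute-force Gaussian-sum oracle", {
  set.seed(2)
  x <- runif(500, 0, 100)
  kd <- kdeDensity(x)
  expect_equal(max(abs(kd$density - kdeOracle(x, kd$grid, kd$bw))), 0,
               tolerance = 1e-12)

  # cross-check against the FFT estimator at coarse tolerance
  d <- density(x, bw = kd$bw, from = 0, to = 100, n = 201)
  expect_lt(max(abs(kd$density - d$y)), 1e-3)
})

test_that("mode detection finds stable and unstable equilibria", {
  grid <- seq(0, 100, 0.5)

  single <- dnorm(grid, 50, 8)
  eq <- findModes(single, grid)
  expect_identical(nrow(eq$stable), 1L)
  expect_identical(nrow(eq$unstable), 0L)
  expect_equal(eq$stable$position, 50)

  # analytic two-Gaussian mixture: derivative roots locate the equilibria
  mix <- function(z) 0.5 * dnorm(z, 20, 10) + 0.5 * dnorm(z, 85, 8)
  dmix <- function(z) (mix(z + 1e-6) - mix(z - 1e-6)) / 2e-6
  m1 <- uniroot(dmix, c(10, 30))$root
  m2 <- uniroot(dmix, c(75, 95))$root
  anti <- uniroot(dmix, c(40, 75))$root
  eq2 <- findModes(mix(grid), grid)
  expect_identical(nrow(eq2$stable), 2L)
  expect_identical(nrow(eq2$unstable), 1L)
  expect_lt(abs(eq2$stable$position[1] - m1), 0.5)
  expect_lt(abs(eq2$stable$position[2] - m2), 0.5)
  expect_lt(abs(eq2$unstable$position[1] - anti), 0.5)

  # everything below the density floor is discarded
  expect_identical(nrow(findModes(single / 100, grid)$stable), 0L)
  expect_error(findModes(numeric(), numeric()), "empty")
})

test_that("sampled mixture modes agree with the analytic roots", {
  set.seed(4)
  n <- 5e4
  pick <- runif(n) < 0.5
  x <- ifelse(pick, rnorm(n, 20, 10), rnorm(n, 85, 8))
  kd <- kdeDensity(x)
  # the KDE estimates the mixture convolved with the kernel
  h <- kd$bw
  smooth <- function(z) {
    0.5 * dnorm(z, 20, sqrt(100 + h^2)) + 0.5 * dnorm(z, 85, sqrt(64 + h^2))
  }
  ds <- function(z) (smooth(z + 1e-6) - smooth(z - 1e-6)) / 2e-6
  want <- c(uniroot(ds, c(10, 30))$root, uniroot(ds, c(75, 95))$root)
  eq <- findModes(kd$density, kd$grid)
  expect_identical(nrow(eq$stable), 2L)
  expect_lt(max(abs(eq$stable$position - want)), 1)
})

test_that("mode counts never increase with the sensitivity parameter", {
  set.seed(5)
  grid <- seq(0, 100, 0.5)
  for (k in 1:10) {
    # random rough density with several bumps
    centres <- runif(sample(2:5, 1), 5, 95)
    w <- runif(length(centres)); w <- w / sum(w)
    dens <- colSums(w * t(sapply(centres, function(c0)
      dnorm(grid, c0, runif(1, 2, 12)))))
    counts <- vapply(c(1e-4, 0.001, 0.01, 0.05, 0.2, 0.5),
                     function(s) {
                       nrow(findModes(dens, grid,
                                      modeConfig(sensitivity = s))$stable)
                     }, integer(1))
    expect_true(all(diff(counts) <= 0))
    # stable and unstable equilibria alternate: always one fewer antimode
    eq <- findModes(dens, grid)
    expect_identical(nrow(eq$unstable), max(0L, nrow(eq$stable) - 1L))
    if (nrow(eq$stable) > 1L) {
      interleaved <- sort(c(eq$stable$position, eq$unstable$position))
      expect_equal(interleaved[seq(1, length(interleaved), 2)],
                   eq$stable$position)
    }
  }
})

test_that("landscape windows report the generator's ground truth", {
  biome <- smallBiome(seed = 8L)
  ls <- buildStabilityLandscape(biome$treeCover, biome$metric,
                                window = windowSpec("map"))
  hasHigh <- vapply(ls@stable, function(s) any(s$position >= 50),
                    logical(1))
  hasLow <- vapply(ls@stable, function(s) any(s$position < 50),
                   logical(1))
  centres <- ls@centres

  # well inside the bistable band: both states; outside: only one
  inner <- ls@usable & centres > 1150 & centres < 1650
  expect_true(all(hasHigh[inner] & hasLow[inner]))
  outer <- ls@usable & (centres < 850 | (centres > 1950 & centres < 2900))
  expect_true(all(xor(hasHigh[outer], hasLow[outer])))

  th <- extractThresholds(ls)
  expect_true(th$detected)
  expect_lt(abs(th$lowerCritical - 1000), 60)
  expect_lt(abs(th$upperCritical - 1800), 60)

  # excluding every bistable pixel leaves no bimodal window
  m <- as.vector(mapValues(biome$metric))
  excl <- cellsToMatrixForTest(m > 1000 & m < 1800, gridOf(biome$metric))
  ls2 <- buildStabilityLandscape(biome$treeCover, biome$metric,
                                 window = windowSpec("map"),
                                 exclusionMask = excl)
  th2 <- extractThresholds(ls2)
  expect_identical(th2$nBimodal, 0L)
  expect_false(th2$detected)
  expect_null(th2$bistableRange)
})

test_that("uniformly forested inputs give a unimodal landscape", {
  cfg <- biomeConfig("map", gridShape = c(60L, 100L),
                     metricRange = c(2000, 3000), seed = 12L)
  g <- gridSpec(60, 100)
  metric <- simulateMetricField(cfg, g)
  set.seed(1)
  tc <- metricMap(matrix(pmin(100, pmax(0, rnorm(6000, 85, 8))), 60),
                  "treecover", g)
  ls <- buildStabilityLandscape(tc, metric, window = windowSpec("map"))
  expect_false(any(vapply(ls@stable[ls@usable],
                          function(s) any(s$position < 50), logical(1))))
  th <- extractThresholds(ls)
  expect_false(th$detected)
})

test_that("sensitivity sweep is monotone and stable across the grid", {
  biome <- smallBiome(seed = 9L)
  sweep <- sensitivitySweep(biome$treeCover, biome$metric,
                            sensitivities = c(0.001, 0.005, 0.01),
                            window = windowSpec("map"))
  expect_identical(nrow(sweep), 3L)
  expect_true(all(diff(sweep$totalModes) <= 0))
  # thresholds shift by at most two window half-widths across the sweep
  expect_lt(max(sweep$lowerCritical) - min(sweep$lowerCritical), 100)
  expect_lt(max(sweep$upperCritical) - min(sweep$upperCritical), 100)

  # vanishing sensitivity reduces to floor-only detection
  biomeS <- simulateBiome(biomeConfig("map", gridShape = c(50L, 100L),
                                      seed = 10L))
  ls0 <- buildStabilityLandscape(
    biomeS$treeCover, biomeS$metric, window = windowSpec("map"),
    modes = modeConfig(sensitivity = 1e-12)
  )
  lsTiny <- buildStabilityLandscape(
    biomeS$treeCover, biomeS$metric, window = windowSpec("map"),
    modes = modeConfig(sensitivity = 1e-9)
  )
  expect_identical(vapply(ls0@stable, nrow, integer(1)),
                   vapply(lsTiny@stable, nrow, integer(1)))
})
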