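#' Silverman's rule-of-thumb bandwidth
#'
#' h = 1.06 * sigma * n^(-1/5), with sigma the sample standard deviation.
#' This is the standard form of the rule; a bandwidth growing with n is
#' not meaningful.
#'
#' @param x numeric sample.
#' @return bandwidth h > 0; requires n >= 2 and sigma > 0.
#' @export
silvermanBandwidth <- function(x) {
  n <- length(x)
  if (n < 2L) stop("Silverman bandwidth requires n >= 2")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("Silverman bandwidth requires sigma > 0")
  1.06 * s * n^(-1 / 5)
}

#' Gaussian kernel density on a fixed evaluation grid
#'
#' Exact Gaussian-sum kernel density estimate,
#' f(g) = mean_i dnorm(g - x_i, sd = h), evaluated on a uniform tree-cover
#' grid (default 0..100 % in 0.5 % steps). The sum is evaluated exactly
#' (no binning), so mode positions are not distorted by an FFT
#' approximation. No boundary correction is applied; mass of modes close
#' to 0 or 100 % leaks outside the physical range, as in the usual
#' ksdensity-style estimator.
#'
#' @param x numeric sample (tree cover, %).
#' @param grid evaluation grid, default \code{seq(0, 100, 0.5)}.
#' @param bw bandwidth; default [silvermanBandwidth()] of \code{x}.
#' @param nMin minimum sample size (default 100); smaller samples error.
#' @return list with \code{grid}, \code{density}, \code{bw}, \code{n}.
#' @export
kdeDensity <- function(x, grid = seq(0, 100, by = 0.5), bw = NULL,
                       nMin = 100L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < nMin) stop("sample size ", n, " below nMin = ", nMin)
  if (is.null(bw)) bw <- silvermanBandwidth(x)
  if (!is.finite(bw) || bw <= 0) stop("bandwidth must be > 0")
  dens <- .gaussKde(x, grid, bw)
  list(grid = grid, density = dens, bw = bw, n = n)
}

#' Mode detection configuration
#'
#' @param densityFloor minimum density for a retained local maximum
#'   (default 0.005).
#' @param sensitivity dimensionless weak-mode filter (default 0.005): a
#'   local maximum is retained only if its topographic prominence is at
#'   least \code{sensitivity} times the global maximum density. Larger
#'   values are stricter; the retained mode count is non-increasing in
#'   this parameter.
#' @return list of class \code{"ModeConfig"}.
#' @export
modeConfig <- function(densityFloor = 0.005, sensitivity = 0.005) {
  stopifnot(densityFloor > 0, sensitivity > 0)
  structure(list(densityFloor = densityFloor, sensitivity = sensitivity),
            class = "ModeConfig")
}

# indices of local maxima on a uniform grid; plateau maxima resolve to
# the leftmost grid point; boundary maxima are kept (tree cover is
# physically bounded at 0 and 100)
localMaxima <- function(d) {
  n <- length(d)
  if (n < 2L) return(integer())
  idx <- integer()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && d[j + 1L] == d[i]) j <- j + 1L   # plateau [i, j]
    leftUp <- i == 1L || d[i - 1L] < d[i]
    rightUp <- j == n || d[j + 1L] < d[i]
    if (leftUp && rightUp) idx <- c(idx, i)
    i <- j + 1L
  }
  idx
}

# topographic prominence of each peak: height minus the higher of the two
# key cols (deepest minima separating the peak from higher terrain on
# each side); the global maximum's prominence is its height
peakProminence <- function(d, peaks) {
  vapply(peaks, function(p) {
    h <- d[p]
    colFor <- function(side) {
      stretch <- if (side < 0) rev(d[seq_len(p - 1L)]) else
        d[seq(p + 1L, length.out = length(d) - p)]
      if (!length(stretch)) return(NA_real_)
      higher <- which(stretch > h)
      if (!length(higher)) return(NA_real_)  # no higher terrain this side
      min(stretch[seq_len(higher[1L])])
    }
    cols <- c(colFor(-1L), colFor(1L))
    if (all(is.na(cols))) h else h - max(cols, na.rm = TRUE)
  }, numeric(1))
}

#' Detect stable and unstable equilibria in a density profile
#'
#' Local maxima of the tree-cover density are stable equilibria; maxima
#' below the density floor, or whose prominence falls below
#' \code{sensitivity} times the global maximum density, are discarded.
#' Between each pair of retained maxima the deepest minimum is the
#' unstable equilibrium (leftmost grid point on ties). Prominences are
#' computed once on the full peak set, so the retained count is
#' non-increasing in the sensitivity parameter.
#'
#' @param density numeric density values on a uniform grid.
#' @param grid the evaluation grid (same length).
#' @param cfg a [modeConfig()].
#' @return list with data.frames \code{stable} and \code{unstable}
#'   (columns \code{position}, \code{density}), sorted by position;
#'   stable and unstable equilibria alternate.
#' @export
findModes <- function(density, grid, cfg = modeConfig()) {
  if (!length(density)) stop("empty density")
  stopifnot(length(density) == length(grid))
  peaks <- localMaxima(density)
  if (length(peaks)) {
    prom <- peakProminence(density, peaks)
    keep <- density[peaks] >= cfg$densityFloor &
      prom >= cfg$sensitivity * max(density)
    peaks <- peaks[keep]
  }
  stable <- data.frame(position = grid[peaks], density = density[peaks])
  unstable <- data.frame(position = numeric(), density = numeric())
  if (length(peaks) > 1L) {
    for (k in seq_len(length(peaks) - 1L)) {
      seg <- seq(peaks[k], peaks[k + 1L])
      at <- seg[which.min(density[seg])]
      unstable <- rbind(unstable,
                        data.frame(position = grid[at],
                                   density = density[at]))
    }
  }
  list(stable = stable, unstable = unstable)
}

#' Moving-window specification for a stability landscape
#'
#' Window centres advance in fixed increments along the climate axis
#' (10 mm yr-1 over 0..3500 for MAP, 10 mm over -800..0 for MCWD, 0.1
#' month over 0..12 for DSL); each window pools pixels within +/-
#' \code{halfWidth} of its centre. Half-widths (50 mm, 25 mm, 0.5 month)
#' are several increments wide so windows hold enough pixels while still
#' resolving the thresholds.
#'
#' @param variable \code{"map"}, \code{"mcwd"} or \code{"dsl"}.
#' @param step increment between window centres (variable units).
#' @param range numeric c(min, max) of window centres.
#' @param halfWidth window half-width (variable units).
#' @param wetterIsLarger orientation of the axis (FALSE for DSL).
#' @return list of class \code{"WindowSpec"}.
#' @export
windowSpec <- function(variable = c("map", "mcwd", "dsl"),
                       step = NULL, range = NULL, halfWidth = NULL,
                       wetterIsLarger = NULL) {
  variable <- match.arg(variable)
  preset <- switch(variable,
    map  = list(step = 10,  range = c(0, 3500), hw = 50,  wet = TRUE),
    mcwd = list(step = 10,  range = c(-800, 0), hw = 25,  wet = TRUE),
    dsl  = list(step = 0.1, range = c(0, 12),   hw = 0.5, wet = FALSE)
  )
  spec <- list(
    variable = variable,
    step = if (is.null(step)) preset$step else step,
    range = if (is.null(range)) preset$range else range,
    halfWidth = if (is.null(halfWidth)) preset$hw else halfWidth,
    wetterIsLarger = if (is.null(wetterIsLarger)) preset$wet
                     else wetterIsLarger
  )
  stopifnot(spec$step > 0, spec$halfWidth >= spec$step / 2,
            diff(spec$range) > 0)
  class(spec) <- "WindowSpec"
  spec
}

#' Empirical stability landscape
#'
#' Per window centre along a climate axis: the stable equilibria (density
#' maxima) and unstable equilibria (antimodes) of the tree-cover
#' distribution, with the pixel count and a usability flag (windows with
#' fewer than \code{nMin} pixels, or degenerate samples, are unusable).
#'
#' @slot variable climate axis name.
#' @slot centres window centres (variable units).
#' @slot nPixels pixels pooled per window.
#' @slot usable logical per window.
#' @slot stable,unstable lists of per-window equilibria data.frames.
#' @slot wetterIsLarger axis orientation.
#' @slot window,modes the [windowSpec()] and [modeConfig()] used.
#' @slot highLowSplit tree-cover % separating low- from high-cover states.
#' @export
setClass("StabilityLandscape",
  representation(
    variable = "character", centres = "numeric", nPixels = "integer",
    usable = "logical", stable = "list", unstable = "list",
    wetterIsLarger = "logical", window = "list", modes = "list",
    highLowSplit = "numeric"
  )
)

setValidity("StabilityLandscape", function(object) {
  k <- length(object@centres)
  if (length(object@nPixels) != k || length(object@usable) != k ||
      length(object@stable) != k || length(object@unstable) != k) {
    return("per-window slots must all have one entry per centre")
  }
  TRUE
})

setMethod("show", "StabilityLandscape", function(object) {
  ns <- vapply(object@stable, nrow, integer(1))
  cat("StabilityLandscape on ", object@variable, ": ",
    length(object@centres), " windows (",
    sum(object@usable), " usable), ",
    sum(object@usable & ns >= 2), " bimodal\n",
    sep = ""
  )
})

#' Build an empirical stability landscape
#'
#' For each window centre, pixels whose climate metric lies within +/-
#' halfWidth are pooled (after removing excluded pixels, e.g. deforested
#' areas), the tree-cover density is estimated by [kdeDensity()] with a
#' Silverman bandwidth, and [findModes()] extracts the equilibria.
#'
#' @param treeCover a [MetricMap-class] (metric \code{"treecover"}) or a
#'   numeric vector of tree-cover values.
#' @param climateMetric a [MetricMap-class] (or numeric vector, paired
#'   with \code{treeCover}) of the window variable.
#' @param window a [windowSpec()].
#' @param modes a [modeConfig()].
#' @param exclusionMask optional logical matrix/vector; TRUE pixels are
#'   excluded before windowing.
#' @param nMin minimum pixels per usable window (default 100).
#' @param evalGrid tree-cover evaluation grid.
#' @param highLowSplit tree cover (%) separating the low- and high-cover
#'   states when thresholds are extracted (default 50).
#' @return a [StabilityLandscape-class].
#' @export
buildStabilityLandscape <- function(treeCover, climateMetric,
                                    window = windowSpec("map"),
                                    modes = modeConfig(),
                                    exclusionMask = NULL,
                                    nMin = 100L,
                                    evalGrid = seq(0, 100, by = 0.5),
                                    highLowSplit = 50) {
  if (is(treeCover, "MetricMap")) {
    if (is(climateMetric, "MetricMap")) {
      assertSameGrid(gridOf(treeCover), gridOf(climateMetric))
    }
    tc <- as.vector(mapValues(treeCover))
  } else tc <- as.numeric(treeCover)
  cm <- if (is(climateMetric, "MetricMap")) {
    as.vector(mapValues(climateMetric))
  } else as.numeric(climateMetric)
  stopifnot(length(tc) == length(cm))
  keep <- is.finite(tc) & is.finite(cm)
  if (!is.null(exclusionMask)) keep <- keep & !as.vector(exclusionMask)
  tc <- tc[keep]; cm <- cm[keep]

  centres <- seq(window$range[1], window$range[2], by = window$step)
  ord <- order(cm)
  cmS <- cm[ord]; tcS <- tc[ord]
  lowIdx <- findInterval(centres - window$halfWidth, cmS, left.open = TRUE)
  highIdx <- findInterval(centres + window$halfWidth, cmS)

  k <- length(centres)
  nPix <- as.integer(highIdx - lowIdx)
  usable <- logical(k)
  stable <- vector("list", k)
  unstable <- vector("list", k)
  empty <- data.frame(position = numeric(), density = numeric())
  for (i in seq_len(k)) {
    stable[[i]] <- empty; unstable[[i]] <- empty
    if (nPix[i] < nMin) next
    x <- tcS[(lowIdx[i] + 1L):highIdx[i]]
    if (stats::sd(x) == 0) next                      # degenerate sample
    kd <- kdeDensity(x, grid = evalGrid, nMin = nMin)
    eq <- findModes(kd$density, kd$grid, modes)
    stable[[i]] <- eq$stable
    unstable[[i]] <- eq$unstable
    usable[i] <- TRUE
  }
  if (!any(usable)) stop("no usable windows")
  new("StabilityLandscape",
    variable = window$variable, centres = centres, nPixels = nPix,
    usable = usable, stable = stable, unstable = unstable,
    wetterIsLarger = window$wetterIsLarger,
    window = unclass(window), modes = unclass(modes),
    highLowSplit = highLowSplit
  )
}

#' Extract critical thresholds and the bistability range
#'
#' Orients the climate axis so that larger means wetter, then finds the
#' contiguous run of windows in which the high-tree-cover state exists
#' that reaches the wet end of the landscape; its dry edge is the lower
#' critical threshold (forest appearance / collapse point). Symmetrically
#' the run of windows holding the low-cover state that reaches the dry
#' end gives the upper critical threshold (wet edge of the bistability
#' range, beyond which the low state no longer exists). The bistability
#' range is the longest contiguous run of bimodal windows; fragmentation
#' of that run is flagged. Results are reported in the metric's own
#' units, numerically ordered (so for MCWD the pair is c(-450, -350)-like,
#' and for DSL the collapse threshold is the upper, drier edge).
#'
#' @param landscape a [StabilityLandscape-class].
#' @return list with \code{lowerCritical}, \code{upperCritical},
#'   \code{bistableRange} (length-2 or NULL when no bimodal window
#'   exists), \code{nBimodal}, \code{fragmented}, \code{detected}.
#' @export
extractThresholds <- function(landscape) {
  use <- landscape@usable
  if (!any(use)) stop("landscape has no usable window")
  split <- landscape@highLowSplit
  hasHigh <- vapply(landscape@stable,
                    function(s) any(s$position >= split), logical(1)) & use
  hasLow <- vapply(landscape@stable,
                   function(s) any(s$position < split), logical(1)) & use
  wet <- if (landscape@wetterIsLarger) landscape@centres else
    -landscape@centres
  o <- order(wet)
  keep <- use[o]                     # usable windows only, dry to wet
  wetO <- wet[o][keep]; highO <- hasHigh[o][keep]; lowO <- hasLow[o][keep]

  # contiguous runs (over the usable subsequence) of a state flag; prefer
  # the run anchored at the relevant end of the axis, fall back to the
  # longest run if the end window itself lacks the state
  anchoredRun <- function(flags, atWetEnd) {
    if (!any(flags)) return(integer())
    r <- rle(flags)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    anchor <- if (atWetEnd) runs[ends[runs] == length(flags)] else
      runs[starts[runs] == 1L]
    best <- if (length(anchor)) anchor else
      runs[which.max(r$lengths[runs])]
    seq(starts[best], ends[best])
  }
  highRun <- anchoredRun(highO, atWetEnd = TRUE)
  lowRun <- anchoredRun(lowO, atWetEnd = FALSE)

  toMetric <- function(w) if (landscape@wetterIsLarger) w else -w
  lowerWet <- if (length(highRun)) min(wetO[highRun]) else NA_real_
  upperWet <- if (length(lowRun)) max(wetO[lowRun]) else NA_real_

  bimodal <- highO & lowO
  nBimodal <- sum(bimodal)
  fragmented <- FALSE
  bistable <- NULL
  if (nBimodal > 0) {
    r <- rle(bimodal)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    fragmented <- length(runs) > 1L
    best <- runs[which.max(r$lengths[runs])]
    wetRange <- range(wetO[starts[best]:ends[best]])
    bistable <- sort(toMetric(wetRange))
  }
  edges <- c(toMetric(lowerWet), toMetric(upperWet))
  lowerCritical <- if (all(is.na(edges))) NA_real_ else
    min(edges, na.rm = TRUE)
  upperCritical <- if (all(is.na(edges))) NA_real_ else
    max(edges, na.rm = TRUE)
  list(
    lowerCritical = lowerCritical,
    upperCritical = upperCritical,
    bistableRange = bistable,
    nBimodal = nBimodal,
    fragmented = fragmented,
    detected = nBimodal > 0
  )
}

#' Sensitivity sweep of the mode filter
#'
#' Re-runs mode detection and threshold extraction for a series of
#' sensitivity-parameter values on one landscape's densities. The
#' retained mode count is non-increasing in the sensitivity value.
#'
#' @param treeCover,climateMetric,window,exclusionMask,nMin as in
#'   [buildStabilityLandscape()].
#' @param sensitivities numeric vector (>= 2 values) to sweep.
#' @param densityFloor density floor held fixed across the sweep.
#' @return data.frame with one row per sensitivity value: thresholds,
#'   bistable-range edges, and the total retained mode count.
#' @export
sensitivitySweep <- function(treeCover, climateMetric,
                             sensitivities = c(0.001, 0.005, 0.01),
                             window = windowSpec("map"),
                             densityFloor = 0.005,
                             exclusionMask = NULL, nMin = 100L) {
  stopifnot(length(sensitivities) >= 2L)
  out <- lapply(sensitivities, function(s) {
    ls <- buildStabilityLandscape(
      treeCover, climateMetric, window = window,
      modes = modeConfig(densityFloor = densityFloor, sensitivity = s),
      exclusionMask = exclusionMask, nMin = nMin
    )
    th <- extractThresholds(ls)
    data.frame(
      sensitivity = s,
      lowerCritical = th$lowerCritical,
      upperCritical = th$upperCritical,
      bistableLow = if (is.null(th$bistableRange)) NA_real_ else
        th$bistableRange[1],
      bistableHigh = if (is.null(th$bistableRange)) NA_real_ else
        th$bistableRange[2],
      totalModes = sum(vapply(ls@stable, nrow, integer(1)))
    )
  })
  do.call(rbind, out)
}
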