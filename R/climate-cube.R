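#' @include grid.R
NULL

#' Monthly climate cube
#'
#' Per-pixel monthly series of precipitation (mm) or temperature (deg C),
#' stored as a cell x year x month array (cells in column-major raster
#' order, 12 months per year). The cube is the in-memory analogue of a
#' CF-style NetCDF stack of monthly grids.
#'
#' @slot values numeric array \code{[nCells, nYears, 12]}.
#' @slot years integer vector of calendar years.
#' @slot varname \code{"precip"} or \code{"temp"}.
#' @slot grid a [GridSpec-class].
#' @slot mask logical vector of length nCells; FALSE cells are ignored by
#'   every metric.
#' @export
setClass("ClimateCube",
  representation(
    values = "array", years = "integer", varname = "character",
    grid = "GridSpec", mask = "logical"
  )
)

setValidity("ClimateCube", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be a 3-d array")
  else {
    if (d[1] != nCells(object@grid))
      msg <- c(msg, "first dimension must equal the number of grid cells")
    if (d[2] != length(object@years))
      msg <- c(msg, "second dimension must equal length(years)")
    if (d[3] != 12L) msg <- c(msg, "cube must have 12 months per year")
  }
  if (!object@varname %in% c("precip", "temp"))
    msg <- c(msg, "varname must be 'precip' or 'temp'")
  if (identical(object@varname, "precip")) {
    v <- object@values[is.finite(object@values)]
    if (length(v) && min(v) < 0) msg <- c(msg, "precipitation must be >= 0")
  }
  if (length(object@mask) != nCells(object@grid))
    msg <- c(msg, "mask length must equal the number of grid cells")
  if (length(msg)) msg else TRUE
})

#' Construct a ClimateCube
#'
#' @param values array \code{[nCells, nYears, 12]}.
#' @param years integer calendar years.
#' @param varname \code{"precip"} or \code{"temp"}.
#' @param grid a [GridSpec-class].
#' @param mask optional logical validity vector (default all TRUE).
#' @return a [ClimateCube-class].
#' @export
climateCube <- function(values, years, varname, grid,
                        mask = rep(TRUE, nCells(grid))) {
  new("ClimateCube",
    values = values, years = as.integer(years), varname = varname,
    grid = grid, mask = mask
  )
}

#' @rdname mapValues
#' @export
cubeValues <- function(x) x@values

#' @rdname mapValues
#' @export
cubeYears <- function(x) x@years

setMethod("show", "ClimateCube", function(object) {
  cat("ClimateCube <", object@varname, "> ",
    nCells(object@grid), " cells x ", length(object@years), " years (",
    min(object@years), "-", max(object@years), ") x 12 months; ",
    sum(!object@mask), " masked cells\n",
    sep = ""
  )
})

#' Annual aggregates of a climate cube
#'
#' \code{annualTotals} sums the 12 months of each year (precipitation);
#' \code{annualMeans} averages them (temperature).
#'
#' @param cube a [ClimateCube-class].
#' @return numeric matrix \code{[nCells, nYears]}; masked cells are NA.
#' @export
annualTotals <- function(cube) {
  out <- rowSums(cube@values, dims = 2)  # sums over the month dimension
  out[!cube@mask, ] <- NA_real_
  out
}

#' @rdname annualTotals
#' @export
annualMeans <- function(cube) {
  out <- rowSums(cube@values, dims = 2) / 12
  out[!cube@mask, ] <- NA_real_
  out
}

# reshape a per-cell vector into the grid's row x col matrix
cellsToMatrix <- function(v, grid) matrix(v, nrow = grid@nrow, ncol = grid@ncol)
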