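#' @import methods
NULL

#' Geographic grid descriptor
#'
#' Describes a regular longitude/latitude grid with pixel-centre
#' registration and north-to-south row order. Every layer participating in
#' a run must share an identical \code{GridSpec}; all container classes in
#' the package carry one and check it.
#'
#' @slot nrow,ncol integer grid dimensions.
#' @slot originLon,originLat longitude/latitude (degrees) of the centre of
#'   the top-left (north-west) pixel.
#' @slot pixelSize pixel size in degrees (square pixels).
#' @export
setClass("GridSpec",
  representation(
    nrow = "integer", ncol = "integer",
    originLon = "numeric", originLat = "numeric",
    pixelSize = "numeric"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nrow) != 1L || is.na(object@nrow) || object@nrow < 1L)
    msg <- c(msg, "nrow must be a positive integer")
  if (length(object@ncol) != 1L || is.na(object@ncol) || object@ncol < 1L)
    msg <- c(msg, "ncol must be a positive integer")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be > 0")
  if (!is.finite(object@originLon) || !is.finite(object@originLat))
    msg <- c(msg, "origin must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param nrow,ncol grid dimensions (pixels).
#' @param originLon,originLat centre of the north-west pixel (degrees).
#' @param pixelSize pixel size in degrees.
#' @return A [GridSpec-class] object.
#' @examples
#' gridSpec(10, 20, originLon = -70, originLat = 0, pixelSize = 0.05)
#' @export
gridSpec <- function(nrow, ncol, originLon = -75, originLat = 5,
                     pixelSize = 0.05) {
  new("GridSpec",
    nrow = as.integer(nrow), ncol = as.integer(ncol),
    originLon = as.numeric(originLon), originLat = as.numeric(originLat),
    pixelSize = as.numeric(pixelSize)
  )
}

#' @describeIn gridSpec number of cells in the grid.
#' @param grid a [GridSpec-class].
#' @export
nCells <- function(grid) as.integer(grid@nrow) * as.integer(grid@ncol)

#' Longitudes and latitudes of pixel centres
#'
#' @param grid a [GridSpec-class].
#' @return \code{cellLon}/\code{cellLat}: a matrix (nrow x ncol) of pixel
#'   centre coordinates in degrees. Rows run north to south.
#' @export
cellLon <- function(grid) {
  lon <- grid@originLon + (seq_len(grid@ncol) - 1) * grid@pixelSize
  matrix(lon, nrow = grid@nrow, ncol = grid@ncol, byrow = TRUE)
}

#' @rdname cellLon
#' @export
cellLat <- function(grid) {
  lat <- grid@originLat - (seq_len(grid@nrow) - 1) * grid@pixelSize
  matrix(lat, nrow = grid@nrow, ncol = grid@ncol)
}

#' Test or assert that two grids are identical
#'
#' All layers of a run must share one grid; this is the single
#' compatibility check reused across the package.
#'
#' @param a,b [GridSpec-class] objects.
#' @param tol numeric tolerance on origin/pixel size.
#' @return \code{sameGrid}: logical. \code{assertSameGrid}: invisibly TRUE,
#'   or an error naming both grids.
#' @export
sameGrid <- function(a, b, tol = 1e-9) {
  a@nrow == b@nrow && a@ncol == b@ncol &&
    abs(a@originLon - b@originLon) < tol &&
    abs(a@originLat - b@originLat) < tol &&
    abs(a@pixelSize - b@pixelSize) < tol
}

#' @rdname sameGrid
#' @export
assertSameGrid <- function(a, b, tol = 1e-9) {
  if (!sameGrid(a, b, tol)) {
    stop(
      "grid mismatch: [", a@nrow, "x", a@ncol, " @ (", a@originLon, ",",
      a@originLat, ") size ", a@pixelSize, "] vs [", b@nrow, "x", b@ncol,
      " @ (", b@originLon, ",", b@originLat, ") size ", b@pixelSize, "]"
    )
  }
  invisible(TRUE)
}

setMethod("show", "GridSpec", function(object) {
  cat(
    "GridSpec: ", object@nrow, " x ", object@ncol, " pixels, ",
    object@pixelSize, " deg, NW centre (", object@originLon, ", ",
    object@originLat, ")\n",
    sep = ""
  )
})

#' Nearest-neighbour regrid of a matrix layer
#'
#' Maps each target pixel centre to the nearest source pixel centre.
#' Intended for harmonising layers that were produced on different grids;
#' a warning is emitted because nearest-neighbour resampling does not
#' conserve area statistics.
#'
#' @param values matrix on \code{from}.
#' @param from,to [GridSpec-class] source and target grids.
#' @return matrix on \code{to}.
#' @export
regridNearest <- function(values, from, to) {
  stopifnot(is.matrix(values), nrow(values) == from@nrow,
            ncol(values) == from@ncol)
  warning("nearest-neighbour regridding: not area-conserving")
  # row index in source for each target row (latitudes decrease southward)
  targetLat <- to@originLat - (seq_len(to@nrow) - 1) * to@pixelSize
  targetLon <- to@originLon + (seq_len(to@ncol) - 1) * to@pixelSize
  rowIdx <- round((from@originLat - targetLat) / from@pixelSize) + 1
  colIdx <- round((targetLon - from@originLon) / from@pixelSize) + 1
  rowIdx <- pmin(pmax(rowIdx, 1L), from@nrow)
  colIdx <- pmin(pmax(colIdx, 1L), from@ncol)
  values[rowIdx, colIdx, drop = FALSE]
}
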