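#' Read and write single-band rasters as ESRI ASCII grids
#'
#' Plain-text ESRI ASCII grid (.asc) with full double precision, so a
#' write-then-read round trip is value-identical (including the NA mask)
#' and carries the full georeference of the [GridSpec-class].
#'
#' @param values numeric matrix on \code{grid}.
#' @param grid a [GridSpec-class].
#' @param path file path.
#' @param naValue nodata sentinel written for NA cells.
#' @return \code{writeAsciiGrid}: invisibly \code{path};
#'   \code{readAsciiGrid}: list with \code{values} and \code{grid}.
#' @export
writeAsciiGrid <- function(values, grid, path, naValue = -9999) {
  stopifnot(is.matrix(values), nrow(values) == grid@nrow,
            ncol(values) == grid@ncol)
  header <- c(
    paste("ncols", grid@ncol),
    paste("nrows", grid@nrow),
    paste("xllcorner", formatC(grid@originLon - grid@pixelSize / 2,
                               format = "g", digits = 17)),
    paste("yllcorner", formatC(
      grid@originLat - (grid@nrow - 1) * grid@pixelSize -
        grid@pixelSize / 2,
      format = "g", digits = 17
    )),
    paste("cellsize", formatC(grid@pixelSize, format = "g", digits = 17)),
    paste("NODATA_value", naValue)
  )
  body <- apply(values, 1, function(r) {
    r[is.na(r)] <- naValue
    paste(formatC(r, format = "g", digits = 17), collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  kv <- stats::setNames(
    vapply(hdr, function(h) as.numeric(h[2]), numeric(1)),
    vapply(hdr, `[`, character(1), 1)
  )
  nr <- as.integer(kv["nrows"]); nc <- as.integer(kv["ncols"])
  vals <- matrix(
    as.numeric(unlist(strsplit(trimws(lines[7:(6 + nr)]), "\\s+"))),
    nrow = nr, byrow = TRUE
  )
  vals[vals == kv["nodata_value"]] <- NA_real_
  grid <- gridSpec(
    nr, nc,
    originLon = kv["xllcorner"] + kv["cellsize"] / 2,
    originLat = kv["yllcorner"] + (nr - 1) * kv["cellsize"] +
      kv["cellsize"] / 2,
    pixelSize = kv["cellsize"]
  )
  list(values = vals, grid = grid)
}

#' Read and write road polylines as GeoJSON
#'
#' Roads are a FeatureCollection of LineStrings in lon/lat (WGS84
#' coordinate order).
#'
#' @param roads list of 2-column lon/lat vertex matrices.
#' @param path file path.
#' @return \code{writeRoadsGeoJSON}: invisibly \code{path};
#'   \code{readRoadsGeoJSON}: list of vertex matrices.
#' @export
writeRoadsGeoJSON <- function(roads, path) {
  features <- lapply(seq_along(roads), function(i) {
    list(
      type = "Feature",
      properties = list(id = i),
      geometry = list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(roads[[i]])), function(k) {
          as.numeric(roads[[i]][k, ])
        })
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeRoadsGeoJSON
#' @export
readRoadsGeoJSON <- function(path) {
  fc <- jsonlite::read_json(path)
  lapply(fc$features, function(f) {
    coords <- f$geometry$coordinates
    m <- do.call(rbind, lapply(coords, function(c2) {
      c(as.numeric(c2[[1]]), as.numeric(c2[[2]]))
    }))
    colnames(m) <- c("lon", "lat")
    m
  })
}
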