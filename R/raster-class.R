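#' @import methods
#' @importFrom stats rnorm runif sd cor quantile setNames lm var
#' @importFrom utils read.csv write.csv head
NULL

# Mean Earth radius (km) used for all spherical area / distance work.
EARTH_RADIUS_KM <- 6371.0088
KM_PER_DEGREE <- pi * EARTH_RADIUS_KM / 180

#' Geographic raster grid
#'
#' A single-band raster on an unprojected longitude/latitude (WGS84) grid.
#' Values are stored as a numeric matrix whose first row is the northernmost
#' row; \code{NA} marks nodata cells. The geotransform is the lower-left
#' corner of the grid (\code{xll}, \code{yll}) plus a square cell size in
#' decimal degrees, the layout used by the Esri ASCII grid format.
#'
#' @slot values numeric matrix, row 1 = top (north) row, \code{NA} = nodata.
#' @slot xll longitude of the lower-left grid corner (degrees).
#' @slot yll latitude of the lower-left grid corner (degrees).
#' @slot cellSize cell size in decimal degrees (square cells).
#'
#' @export
setClass("RasterGrid",
  representation(values = "matrix", xll = "numeric", yll = "numeric",
                 cellSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
    if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
        object@cellSize <= 0)
      msg <- c(msg, "cellSize must be a single positive number")
    if (length(object@xll) != 1 || length(object@yll) != 1 ||
        !is.finite(object@xll) || !is.finite(object@yll))
      msg <- c(msg, "xll/yll must be single finite numbers")
    v <- object@values
    if (any(is.infinite(v))) msg <- c(msg, "values must be finite or NA")
    if (length(msg)) msg else TRUE
  })

#' Construct a RasterGrid
#'
#' @param values numeric matrix (row 1 = northernmost row, NA = nodata).
#' @param xll,yll lower-left corner of the grid in decimal degrees.
#' @param cellSize cell size in decimal degrees.
#' @return A \linkS4class{RasterGrid}.
#' @export
rasterGrid <- function(values, xll, yll, cellSize) {
  new("RasterGrid", values = values, xll = xll, yll = yll,
      cellSize = cellSize)
}

#' @rdname rasterGrid
#' @param x a \code{RasterGrid}
#' @export
gridValues <- function(x) x@values

#' @rdname rasterGrid
#' @export
nRows <- function(x) nrow(x@values)

#' @rdname rasterGrid
#' @export
nCols <- function(x) ncol(x@values)

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid: %d x %d cells, %.6g deg resolution\n",
              nrow(v), ncol(v), object@cellSize))
  cat(sprintf("  extent: lon [%.4f, %.4f], lat [%.4f, %.4f]\n",
              object@xll, object@xll + ncol(v) * object@cellSize,
              object@yll, object@yll + nrow(v) * object@cellSize))
  ok <- v[is.finite(v)]
  cat(sprintf("  land cells: %d / %d", length(ok), length(v)))
  if (length(ok))
    cat(sprintf(", value range [%.4g, %.4g]", min(ok), max(ok)))
  cat("\n")
})

# Longitudes of cell centers, west to east.
cellLons <- function(x) x@xll + (seq_len(nCols(x)) - 0.5) * x@cellSize

# Latitudes of cell centers in matrix row order (row 1 = north).
cellLats <- function(x) {
  nr <- nRows(x)
  x@yll + (nr - seq_len(nr) + 0.5) * x@cellSize
}

sameGeometry <- function(a, b, tol = 1e-9) {
  nRows(a) == nRows(b) && nCols(a) == nCols(b) &&
    abs(a@xll - b@xll) < tol && abs(a@yll - b@yll) < tol &&
    abs(a@cellSize - b@cellSize) < tol
}

# Row/col of the cell containing a point; half-open cells [edge, edge+size).
# Returns NA for points off the grid.
pointToCell <- function(x, lon, lat) {
  col <- floor((lon - x@xll) / x@cellSize) + 1L
  rowFromBottom <- floor((lat - x@yll) / x@cellSize) + 1L
  row <- nRows(x) - rowFromBottom + 1L
  bad <- col < 1L | col > nCols(x) | row < 1L | row > nRows(x)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' Spherical cell areas by grid row
#'
#' Area in km^2 of one cell in each row of a geographic grid, from the exact
#' spherical formula \eqn{A = R^2 \Delta\lambda (\sin\phi_t - \sin\phi_b)}
#' with R = 6371.0088 km. All cells in a row share the same area.
#'
#' @param x a \linkS4class{RasterGrid}.
#' @return Numeric vector of length \code{nRows(x)} (km^2), in matrix row
#'   order (north first).
#' @export
cellAreas <- function(x) {
  nr <- nRows(x)
  latTop <- x@yll + (nr - seq_len(nr) + 1) * x@cellSize
  latBot <- latTop - x@cellSize
  dlam <- x@cellSize * pi / 180
  EARTH_RADIUS_KM^2 * dlam * (sin(latTop * pi / 180) - sin(latBot * pi / 180))
}

# Total area (km^2) of cells where mask is TRUE (matrix of logicals).
maskArea <- function(x, mask) {
  areas <- cellAreas(x)
  sum(rowSums(mask & !is.na(mask)) * areas)
}

#' Read / write Esri ASCII grids
#'
#' Minimal reader and writer for the Esri ASCII (.asc) raster format,
#' honoring \code{NODATA_value} and both \code{xllcorner} and
#' \code{xllcenter} header conventions.
#'
#' @param path file path.
#' @return \code{readAsc} returns a \linkS4class{RasterGrid}.
#' @export
readAsc <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  nHdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nHdr <- nHdr + 1L
    } else break
  }
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = nHdr, quiet = TRUE)
  stopifnot(length(vals) == ncols * nrows)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA
  rasterGrid(m, xll, yll, cs)
}

#' @rdname readAsc
#' @param x a \linkS4class{RasterGrid} to write.
#' @param nodata value written for NA cells.
#' @export
writeAsc <- function(x, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nCols(x)),
    sprintf("nrows %d", nRows(x)),
    sprintf("xllcorner %.10g", x@xll),
    sprintf("yllcorner %.10g", x@yll),
    sprintf("cellsize %.10g", x@cellSize),
    sprintf("NODATA_value %g", nodata)), con)
  m <- x@values
  m[is.na(m)] <- nodata
  for (i in seq_len(nrow(m)))
    writeLines(paste(format(m[i, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  invisible(path)
}

#' Resample a raster onto a target grid
#'
#' Re-grids a layer onto the geometry of a template grid by nearest-neighbour
#' cell lookup or bilinear interpolation between the four surrounding cell
#' centers. Nodata propagates: a bilinear result is NA when any contributing
#' source cell is NA.
#'
#' @param layer source \linkS4class{RasterGrid}.
#' @param template \linkS4class{RasterGrid} supplying the target geometry.
#' @param method \code{"nearest"} or \code{"bilinear"}.
#' @return A \linkS4class{RasterGrid} on the template geometry.
#' @export
resampleToGrid <- function(layer, template, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  sLonMin <- layer@xll; sLonMax <- layer@xll + nCols(layer) * layer@cellSize
  sLatMin <- layer@yll; sLatMax <- layer@yll + nRows(layer) * layer@cellSize
  tLonMin <- template@xll
  tLonMax <- template@xll + nCols(template) * template@cellSize
  tLatMin <- template@yll
  tLatMax <- template@yll + nRows(template) * template@cellSize
  if (tLonMin >= sLonMax || tLonMax <= sLonMin ||
      tLatMin >= sLatMax || tLatMax <= sLatMin)
    stop("source and target extents are disjoint")

  lons <- cellLons(template)
  lats <- cellLats(template)
  out <- matrix(NA_real_, nRows(template), nCols(template))
  src <- layer@values
  if (method == "nearest") {
    for (i in seq_len(nRows(template))) {
      rc <- pointToCell(layer, lons, rep(lats[i], length(lons)))
      ok <- !is.na(rc[, 1])
      out[i, ok] <- src[cbind(rc[ok, 1], rc[ok, 2])]
    }
  } else {
    sLons <- cellLons(layer)
    sLats <- rev(cellLats(layer))  # ascending for interpolation
    srcAsc <- src[rev(seq_len(nrow(src))), , drop = FALSE]
    for (i in seq_len(nRows(template))) {
      for (j in seq_len(nCols(template))) {
        lon <- lons[j]; lat <- lats[i]
        cj <- findInterval(lon, sLons)
        ci <- findInterval(lat, sLats)
        cj0 <- min(max(cj, 1L), length(sLons) - 1L)
        ci0 <- min(max(ci, 1L), length(sLats) - 1L)
        if (length(sLons) == 1L || length(sLats) == 1L) next
        tx <- (lon - sLons[cj0]) / (sLons[cj0 + 1] - sLons[cj0])
        ty <- (lat - sLats[ci0]) / (sLats[ci0 + 1] - sLats[ci0])
        tx <- min(max(tx, 0), 1); ty <- min(max(ty, 0), 1)
        z <- srcAsc[ci0:(ci0 + 1), cj0:(cj0 + 1)]
        if (any(is.na(z))) next
        out[i, j] <- (1 - ty) * ((1 - tx) * z[1, 1] + tx * z[1, 2]) +
          ty * ((1 - tx) * z[2, 1] + tx * z[2, 2])
      }
    }
  }
  rasterGrid(out, template@xll, template@yll, template@cellSize)
}
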