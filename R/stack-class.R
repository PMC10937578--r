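#' Stack of co-registered predictor rasters
#'
#' Named environmental predictor layers sharing a single geotransform and
#' nodata mask. Layers are stored as matrices (row 1 = north); a cell is
#' land only if it is non-NA in every layer.
#'
#' @slot layers named list of numeric matrices with identical dimensions.
#' @slot xll,yll lower-left grid corner (decimal degrees).
#' @slot cellSize cell size in decimal degrees.
#'
#' @export
setClass("PredictorStack",
  representation(layers = "list", xll = "numeric", yll = "numeric",
                 cellSize = "numeric"),
  validity = function(object) {
    msg <- character()
    ls <- object@layers
    if (length(ls) == 0) msg <- c(msg, "stack must contain >= 1 layer")
    nm <- names(ls)
    if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
      msg <- c(msg, "layers must have unique non-empty names")
    dims <- vapply(ls, function(m) c(nrow(m), ncol(m)), numeric(2))
    if (length(ls) && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
      msg <- c(msg, "all layers must share the same dimensions")
    if (object@cellSize <= 0) msg <- c(msg, "cellSize must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct a PredictorStack
#'
#' @param layers named list of matrices, or of \linkS4class{RasterGrid}s
#'   sharing a geometry.
#' @param xll,yll,cellSize geotransform (ignored when RasterGrids are given).
#' @return A \linkS4class{PredictorStack}.
#' @export
predictorStack <- function(layers, xll = NULL, yll = NULL, cellSize = NULL) {
  if (length(layers) && is(layers[[1]], "RasterGrid")) {
    g <- layers[[1]]
    for (l in layers) if (!sameGeometry(g, l))
      stop("layers are not co-registered")
    xll <- g@xll; yll <- g@yll; cellSize <- g@cellSize
    layers <- lapply(layers, gridValues)
  }
  new("PredictorStack", layers = layers, xll = xll, yll = yll,
      cellSize = cellSize)
}

#' @rdname predictorStack
#' @param x a \code{PredictorStack}
#' @export
layerNames <- function(x) names(x@layers)

#' @rdname predictorStack
#' @export
nLayers <- function(x) length(x@layers)

#' @rdname predictorStack
#' @param name layer name
#' @export
getLayer <- function(x, name) {
  if (!name %in% names(x@layers)) stop("no layer named '", name, "'")
  rasterGrid(x@layers[[name]], x@xll, x@yll, x@cellSize)
}

#' @rdname predictorStack
#' @export
landMask <- function(x) {
  m <- !is.na(x@layers[[1]])
  for (l in x@layers[-1]) m <- m & !is.na(l)
  m
}

#' @rdname predictorStack
#' @details \code{stackValues} returns the cell-by-layer value matrix for the
#'   given linear cell indices (default: all land cells, column-major order).
#' @param cells linear cell indices into the layer matrices.
#' @export
stackValues <- function(x, cells = NULL) {
  if (is.null(cells)) cells <- which(landMask(x))
  out <- vapply(x@layers, function(m) m[cells], numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1,
                                         dimnames = list(NULL, names(x@layers)))
  out
}

setMethod("show", "PredictorStack", function(object) {
  d <- dim(object@layers[[1]])
  cat(sprintf("PredictorStack: %d layers, %d x %d cells, %.6g deg\n",
              nLayers(object), d[1], d[2], object@cellSize))
  cat("  layers:", paste(layerNames(object), collapse = ", "), "\n")
  cat(sprintf("  land cells: %d / %d\n", sum(landMask(object)),
              prod(d)))
})

# Template RasterGrid with the stack's geometry and the land mask applied.
stackTemplate <- function(x, fill = NA_real_) {
  m <- matrix(fill, nrow(x@layers[[1]]), ncol(x@layers[[1]]))
  m[!landMask(x)] <- NA
  rasterGrid(m, x@xll, x@yll, x@cellSize)
}

#' Write all stack layers as Esri ASCII grids
#'
#' @param x a \linkS4class{PredictorStack}.
#' @param dir output directory (created if needed); one
#'   \code{<layer>.asc} per layer.
#' @return Invisibly, the written paths.
#' @export
writeStackAsc <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(layerNames(x), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    writeAsc(getLayer(x, nm), p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a directory of Esri ASCII grids as a stack
#'
#' @param paths character vector of .asc files; layer names are the file
#'   names without extension.
#' @return A \linkS4class{PredictorStack}.
#' @export
readStackAsc <- function(paths) {
  grids <- lapply(paths, readAsc)
  names(grids) <- sub("\\.asc$", "", basename(paths))
  predictorStack(grids)
}
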