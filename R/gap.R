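# Protected-area overlay and conservation-gap accounting.

#' Rasterize polygons onto a template grid
#'
#' A cell is marked protected iff its center lies inside any polygon
#' (even-odd ray casting; vertices/edges resolve by the half-open crossing
#' rule). Nodata cells of the template stay nodata.
#'
#' @param polygons a \code{polygonSet} (list of closed lon/lat ring
#'   matrices), e.g. from \code{\link{generateProtectedAreas}} or
#'   \code{\link{readGeoJson}}.
#' @param template \linkS4class{RasterGrid} supplying geometry and land
#'   mask.
#' @return Binary \linkS4class{RasterGrid} (1 = protected) with attribute
#'   \code{nPolygons}.
#' @export
rasterizePolygons <- function(polygons, template) {
  lons <- cellLons(template); lats <- cellLats(template)
  inside <- matrix(FALSE, nRows(template), nCols(template))
  for (ring in polygons) {
    rx <- ring[, 1]; ry <- ring[, 2]
    # quick bounding-box reject per polygon
    ci <- which(lons >= min(rx) & lons <= max(rx))
    rowsHit <- which(lats >= min(ry) & lats <= max(ry))
    if (!length(ci) || !length(rowsHit)) next
    nV <- length(rx) - 1L
    for (i in rowsHit) {
      y <- lats[i]
      crossX <- numeric(0)
      for (v in seq_len(nV)) {
        y1 <- ry[v]; y2 <- ry[v + 1]
        if ((y1 <= y) != (y2 <= y)) {
          crossX <- c(crossX,
                      rx[v] + (y - y1) / (y2 - y1) * (rx[v + 1] - rx[v]))
        }
      }
      if (!length(crossX)) next
      crossX <- sort(crossX)
      cnt <- vapply(lons[ci], function(x) sum(crossX > x), integer(1))
      inside[i, ci] <- inside[i, ci] | (cnt %% 2L == 1L)
    }
  }
  out <- ifelse(is.na(template@values), NA_real_, as.numeric(inside))
  out <- rasterGrid(out, template@xll, template@yll, template@cellSize)
  attr(out, "nPolygons") <- length(polygons)
  out
}

#' Conservation-gap summary from areas
#'
#' The bookkeeping step of a gap analysis: gap = priority - overlap,
#' percent unprotected = 100 * gap / priority, and the verdict compares
#' the protected share of the priority area with the conservation target.
#'
#' @param priorityKm2 priority-area extent (km^2).
#' @param overlapKm2 extent of priority area inside protected areas (km^2).
#' @param targetFraction conservation target as a fraction (default 0.30).
#' @return List of class \code{"gapReport"}: priorityKm2, overlapKm2,
#'   gapKm2, percentUnprotected, percentProtected, targetMet.
#' @export
gapSummary <- function(priorityKm2, overlapKm2, targetFraction = 0.30) {
  if (priorityKm2 <= 0) stop("priority area must be positive")
  if (overlapKm2 < 0 || overlapKm2 > priorityKm2 * (1 + 1e-9))
    stop("overlap must lie within [0, priority area]")
  gap <- priorityKm2 - overlapKm2
  pctUn <- 100 * gap / priorityKm2
  structure(list(priorityKm2 = priorityKm2, overlapKm2 = overlapKm2,
                 gapKm2 = gap, percentUnprotected = pctUn,
                 percentProtected = 100 - pctUn,
                 targetFraction = targetFraction,
                 targetMet = (100 - pctUn) / 100 >= targetFraction),
            class = "gapReport")
}

#' Gap analysis of a priority mask against a protected-area mask
#'
#' Overlap is the area-weighted intersection of the priority and protected
#' masks; the gap (conservation vacancy) is the priority area outside
#' protection.
#'
#' @param priority binary priority-area \linkS4class{RasterGrid} (e.g.
#'   \code{\link{solutionRaster}} output).
#' @param protected binary protected-area \linkS4class{RasterGrid},
#'   co-registered with \code{priority}.
#' @param targetFraction conservation target (default 0.30).
#' @return A \code{gapReport} (see \code{\link{gapSummary}}) with the
#'   additional entries \code{protectedKm2} (total protected area) and
#'   \code{gapMask}.
#' @export
gapReport <- function(priority, protected, targetFraction = 0.30) {
  if (!sameGeometry(priority, protected))
    stop("masks are not co-registered")
  p <- priority@values == 1 & !is.na(priority@values)
  if (!any(p)) stop("priority mask is empty")
  q <- protected@values == 1 & !is.na(protected@values)
  rep <- gapSummary(maskArea(priority, p), maskArea(priority, p & q),
                    targetFraction)
  rep$protectedKm2 <- maskArea(priority, q)
  gm <- ifelse(is.na(priority@values), NA_real_, as.numeric(p & !q))
  rep$gapMask <- rasterGrid(gm, priority@xll, priority@yll,
                            priority@cellSize)
  rep
}

#' @export
print.gapReport <- function(x, ...) {
  cat(sprintf("gapReport: priority %.2f km2, overlap %.2f km2, gap %.2f km2\n",
              x$priorityKm2, x$overlapKm2, x$gapKm2))
  cat(sprintf("  %.2f%% of the priority area unprotected; target %.0f%% %s\n",
              x$percentUnprotected, 100 * x$targetFraction,
              if (x$targetMet) "met" else "NOT met"))
  invisible(x)
}

#' Write a gap report as JSON and CSV
#'
#' @param report a \code{gapReport}.
#' @param stem output path stem (writes \code{<stem>.json} and
#'   \code{<stem>.csv}).
#' @export
writeGapReport <- function(report, stem) {
  flat <- report[c("priorityKm2", "overlapKm2", "gapKm2",
                   "percentUnprotected", "percentProtected", "targetMet")]
  jsonlite::write_json(flat, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write.csv(as.data.frame(flat), paste0(stem, ".csv"), row.names = FALSE)
  invisible(stem)
}

#' Read / write polygon collections as GeoJSON
#'
#' Supports Polygon and MultiPolygon features (outer rings only; holes are
#' ignored on read with a warning).
#'
#' @param path GeoJSON file path.
#' @return \code{readGeoJson} returns a \code{polygonSet} (list of closed
#'   lon/lat ring matrices).
#' @export
readGeoJson <- function(path) {
  g <- jsonlite::read_json(path)
  feats <- if (identical(g$type, "FeatureCollection")) g$features
           else list(g)
  rings <- list(); holes <- 0L
  toRing <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    colnames(m) <- c("lon", "lat")
    m
  }
  for (f in feats) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    if (identical(geom$type, "Polygon")) {
      rings[[length(rings) + 1L]] <- toRing(geom$coordinates[[1]])
      holes <- holes + length(geom$coordinates) - 1L
    } else if (identical(geom$type, "MultiPolygon")) {
      for (poly in geom$coordinates) {
        rings[[length(rings) + 1L]] <- toRing(poly[[1]])
        holes <- holes + length(poly) - 1L
      }
    }
  }
  if (holes > 0) warning(holes, " interior ring(s) ignored")
  structure(rings, class = "polygonSet")
}

#' @rdname readGeoJson
#' @param polygons a \code{polygonSet}.
#' @export
writeGeoJson <- function(polygons, path) {
  feats <- lapply(seq_along(polygons), function(i) {
    ring <- polygons[[i]]
    list(type = "Feature", properties = list(id = i),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(r) c(ring[r, 1], ring[r, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
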