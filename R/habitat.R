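# Habitat classification, binary maps, spherical area accounting, change
# maps, centroids and range-shift distances.

HABITAT_CLASSES <- c("unsuitable", "slightly", "moderately", "optimally")
DEFAULT_BREAKS <- c(0.1, 0.24, 0.5)
DEFAULT_THRESHOLD <- 0.24  # documented binarization default (MTSS on the
                           # source analysis); use mtssThreshold() when a
                           # fitted model is available

#' Classify a suitability raster into habitat classes
#'
#' Class k covers \code{[break_k, break_k+1)} with the top interval closed
#' at 1: 0 unsuitable, 1 slightly, 2 moderately, 3 optimally suitable under
#' the default breaks 0.1 / 0.24 / 0.5. Nodata propagates.
#'
#' @param suitability \linkS4class{RasterGrid} with values in [0, 1].
#' @param breaks strictly increasing interior break points in (0, 1).
#' @return List of class \code{"habitatClassMap"}: \code{map} (integer-coded
#'   \linkS4class{RasterGrid}), \code{breaks}, \code{classes}.
#' @export
classifySuitability <- function(suitability, breaks = DEFAULT_BREAKS) {
  if (is.unsorted(breaks, strictly = TRUE) ||
      any(breaks <= 0) || any(breaks >= 1))
    stop("breaks must be strictly increasing within (0, 1)")
  v <- suitability@values
  ok <- !is.na(v)
  if (any(v[ok] < 0 | v[ok] > 1)) stop("suitability values must lie in [0, 1]")
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  cls[ok] <- findInterval(v[ok], breaks)  # [b_k, b_{k+1}), top closed at 1
  structure(list(
    map = rasterGrid(cls, suitability@xll, suitability@yll,
                     suitability@cellSize),
    breaks = breaks, classes = HABITAT_CLASSES),
    class = "habitatClassMap")
}

#' Exact Fisher-Jenks natural breaks
#'
#' Dynamic-programming minimization of within-class sum of squared
#' deviations; exact for the given values (intended for moderate n).
#'
#' @param values numeric vector.
#' @param k number of classes.
#' @return Numeric vector of k-1 interior break points (upper bounds of the
#'   lower classes, placed at class boundaries' midpoints).
#' @export
jenksBreaks <- function(values, k) {
  x <- sort(values[is.finite(values)])
  n <- length(x)
  if (k < 2 || k > n) stop("need 2 <= k <= n")
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssq <- function(i, j) {  # within-class sum of squares for x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n); B <- matrix(0L, k, n)
  for (j in seq_len(n)) D[1, j] <- ssq(1, j)
  for (c in 2:k) for (j in c:n) {
    for (i in c:j) {
      val <- D[c - 1, i - 1] + ssq(i, j)
      if (val < D[c, j]) { D[c, j] <- val; B[c, j] <- i }
    }
  }
  cuts <- integer(k - 1); j <- n
  for (c in k:2) { i <- B[c, j]; cuts[c - 1] <- i - 1L; j <- i - 1L }
  (x[cuts] + x[cuts + 1]) / 2
}

#' MTSS binarization threshold
#'
#' The score maximizing training sensitivity plus specificity; delegates to
#' the exact threshold scan of \code{\link{maxTSS}}.
#'
#' @param presScores,bgScores training presence and background scores.
#' @return The maximizing threshold (smallest if tied).
#' @export
mtssThreshold <- function(presScores, bgScores) {
  maxTSS(presScores, bgScores)$threshold
}

#' Binarize a suitability raster
#'
#' 1 where value is strictly greater than the threshold, else 0; nodata
#' propagates. (Note the one-cell difference from
#' \code{\link{classifySuitability}}, which closes intervals on the left.)
#'
#' @param suitability \linkS4class{RasterGrid}.
#' @param threshold value in [0, 1] (default 0.24).
#' @return Binary \linkS4class{RasterGrid}.
#' @export
binarize <- function(suitability, threshold = DEFAULT_THRESHOLD) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  v <- suitability@values
  out <- ifelse(is.na(v), NA_real_, as.numeric(v > threshold))
  rasterGrid(out, suitability@xll, suitability@yll, suitability@cellSize)
}

#' Per-class area report
#'
#' Spherical areas (km^2) and percentages of the land area per habitat
#' class; total suitable habitat is the sum of the moderately and optimally
#' suitable classes.
#'
#' @param classMap a \code{habitatClassMap}.
#' @return data.frame (class, areaKm2, percent) with attribute
#'   \code{totalSuitableKm2}.
#' @export
classAreaReport <- function(classMap) {
  m <- classMap$map@values
  areas <- cellAreas(classMap$map)
  perClass <- vapply(0:3, function(k)
    sum(rowSums(!is.na(m) & m == k) * areas), numeric(1))
  total <- sum(perClass)
  out <- data.frame(class = HABITAT_CLASSES, areaKm2 = perClass,
                    percent = 100 * perClass / total)
  attr(out, "totalSuitableKm2") <- perClass[3] + perClass[4]
  attr(out, "landAreaKm2") <- total
  out
}

#' Change map between two binary suitability rasters
#'
#' Codes: 0 stable-unsuitable, 1 gain (0 to 1), 2 loss (1 to 0),
#' 3 stable-suitable. Reports areas and percents of each category plus
#' percent gain/loss relative to the current suitable area.
#'
#' @param current,future co-registered binary \linkS4class{RasterGrid}s.
#' @return List of class \code{"changeMap"}: \code{map}, \code{areas}
#'   (data.frame), \code{pctGainOfCurrent}, \code{pctLossOfCurrent}.
#' @export
changeMap <- function(current, future) {
  if (!sameGeometry(current, future)) stop("grids are not co-registered")
  a <- current@values; b <- future@values
  code <- matrix(NA_real_, nrow(a), ncol(a))
  ok <- !is.na(a) & !is.na(b)
  code[ok] <- ifelse(a[ok] == 0 & b[ok] == 0, 0,
              ifelse(a[ok] == 0 & b[ok] == 1, 1,
              ifelse(a[ok] == 1 & b[ok] == 0, 2, 3)))
  grid <- rasterGrid(code, current@xll, current@yll, current@cellSize)
  areas <- cellAreas(grid)
  catArea <- vapply(0:3, function(k)
    sum(rowSums(!is.na(code) & code == k) * areas), numeric(1))
  land <- sum(catArea)
  curSuit <- catArea[3] + catArea[4]  # loss + stable-suitable
  out <- data.frame(
    category = c("stable-unsuitable", "gain", "loss", "stable-suitable"),
    areaKm2 = catArea, percent = 100 * catArea / land)
  structure(list(map = grid, areas = out,
                 pctGainOfCurrent = if (curSuit > 0)
                   100 * catArea[2] / curSuit else NA_real_,
                 pctLossOfCurrent = if (curSuit > 0)
                   100 * catArea[3] / curSuit else NA_real_),
            class = "changeMap")
}

#' Area-weighted centroid of a binary raster
#'
#' The spherical-area-weighted mean of the suitable cells' center
#' coordinates; optionally weighted by a continuous suitability surface.
#'
#' @param binary binary \linkS4class{RasterGrid} (1 = suitable).
#' @param weights optional \linkS4class{RasterGrid} of weights multiplied
#'   into the cell areas (e.g. suitability).
#' @return List of class \code{"centroid"}: \code{longitude},
#'   \code{latitude}.
#' @export
rangeCentroid <- function(binary, weights = NULL) {
  v <- binary@values
  suit <- which(!is.na(v) & v == 1, arr.ind = TRUE)
  if (nrow(suit) == 0) stop("no suitable cells")
  w <- cellAreas(binary)[suit[, 1]]
  if (!is.null(weights)) {
    stopifnot(sameGeometry(binary, weights))
    w <- w * weights@values[suit]
  }
  lons <- cellLons(binary)[suit[, 2]]
  lats <- cellLats(binary)[suit[, 1]]
  structure(list(longitude = sum(w * lons) / sum(w),
                 latitude = sum(w * lats) / sum(w)),
            class = "centroid")
}

#' Geodesic distance between two centroids
#'
#' WGS84 ellipsoid distance (geosphere) by default; great-circle haversine
#' with R = 6371.0088 km as an option. The two agree within about 0.5
#' percent.
#'
#' @param c1,c2 \code{centroid} objects or \code{c(lon, lat)} vectors.
#' @param method \code{"geodesic"} or \code{"haversine"}.
#' @return Distance in metres.
#' @export
centroidShift <- function(c1, c2, method = c("geodesic", "haversine")) {
  method <- match.arg(method)
  p <- function(c) if (inherits(c, "centroid"))
    c(c$longitude, c$latitude) else c
  if (method == "geodesic") geosphere::distGeo(p(c1), p(c2))
  else geosphere::distHaversine(p(c1), p(c2), r = EARTH_RADIUS_KM * 1000)
}

#' Scenario centroid table with shift distances
#'
#' @param centroids named list of \code{centroid} objects; the first entry
#'   is the reference (current) scenario.
#' @param method passed to \code{\link{centroidShift}}.
#' @return data.frame: scenario, longitude, latitude, shiftM (metres from
#'   the reference; 0 for the reference itself).
#' @export
centroidTable <- function(centroids, method = "geodesic") {
  ref <- centroids[[1]]
  data.frame(
    scenario = names(centroids),
    longitude = vapply(centroids, function(c) c$longitude, numeric(1)),
    latitude = vapply(centroids, function(c) c$latitude, numeric(1)),
    shiftM = vapply(centroids, function(c)
      centroidShift(ref, c, method), numeric(1)),
    row.names = NULL)
}
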