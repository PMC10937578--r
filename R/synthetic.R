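# Synthetic landscapes: spatially autocorrelated predictors with controlled
# collinearity, a smooth unimodal "true" niche, occurrence samples drawn
# proportionally to true suitability, and rectangular protected areas.
# These supply every downstream stage with inputs of known structure.

DEFAULT_PREDICTORS <- c("Bio3", "Bio4", "Bio5", "Bio6", "Bio8", "Bio12",
                        "Bio13", "slope", "T_bs", "T_esp", "T_cec_soil",
                        "T_cec_clay")

#' Landscape configuration
#'
#' Parameters of the synthetic landscape: grid geometry, the Gaussian
#' smoothing range inducing spatial autocorrelation, the predictor set and
#' any collinear pairs to induce. The default emits 14 layers — the 12
#' canonical bioclim/soil/terrain predictors plus two extra bioclim layers
#' (Bio1, Bio11) made collinear with Bio4 and Bio6 — so that collinearity
#' screening has real work to do and can reduce the set to 12.
#'
#' @param nRows,nCols grid dimensions (>= 8).
#' @param originLon,originLat lower-left corner, decimal degrees.
#' @param cellSize cell size in decimal degrees (default 0.05, roughly the
#'   5-km working resolution of a 2.5 arc-minute analysis).
#' @param autocorrRange Gaussian smoothing sigma in cells (> 0).
#' @param predictorNames character vector of layer names.
#' @param collinearPairs data.frame with columns \code{source},
#'   \code{target} (layer indices) and \code{rho} (target Pearson
#'   correlation in [-1, 1]); the target layer is rebuilt as a noisy copy of
#'   the source.
#' @param seed integer RNG seed.
#' @return A list of class \code{"landscapeConfig"}.
#' @export
landscapeConfig <- function(nRows = 100L, nCols = 100L,
                            originLon = 105, originLat = 30,
                            cellSize = 0.05, autocorrRange = 6,
                            predictorNames = c(DEFAULT_PREDICTORS,
                                               "Bio1", "Bio11"),
                            collinearPairs = data.frame(
                              source = c(2L, 4L), target = c(13L, 14L),
                              rho = c(0.85, 0.9)),
                            seed = 1L) {
  if (nRows < 8 || nCols < 8) stop("nRows and nCols must be >= 8")
  if (cellSize <= 0) stop("cellSize must be positive")
  if (autocorrRange <= 0) stop("autocorrRange must be positive")
  if (nrow(collinearPairs) && any(abs(collinearPairs$rho) > 1))
    stop("collinear target correlations must lie in [-1, 1]")
  if (nrow(collinearPairs) &&
      any(c(collinearPairs$source, collinearPairs$target) >
          length(predictorNames)))
    stop("collinear pair indices exceed the predictor count")
  structure(list(nRows = as.integer(nRows), nCols = as.integer(nCols),
                 originLon = originLon, originLat = originLat,
                 cellSize = cellSize, autocorrRange = autocorrRange,
                 predictorNames = predictorNames,
                 collinearPairs = collinearPairs, seed = as.integer(seed)),
            class = "landscapeConfig")
}

# 1-D Gaussian smoothing matrix (n x n), kernel truncated at 3 sigma and
# renormalized row-wise, so edges keep unit weight.
gaussSmoothMatrix <- function(n, sigma) {
  idx <- seq_len(n)
  d <- outer(idx, idx, "-")
  k <- exp(-d^2 / (2 * sigma^2))
  k[abs(d) > ceiling(3 * sigma)] <- 0
  k / rowSums(k)
}

standardizeField <- function(m) (m - mean(m)) / sd(as.vector(m))

#' Generate spatially autocorrelated predictor rasters
#'
#' Each layer is Gaussian white noise smoothed with a separable Gaussian
#' kernel of sigma \code{autocorrRange} cells, then standardized to mean 0 /
#' sd 1 over all cells. Collinear pairs are induced afterwards by mixing a
#' copy of the (standardized) source layer with the target's own independent
#' field at the analytically required ratio
#' \eqn{y = \rho x + \sqrt{1-\rho^2}\, z}, giving expected Pearson
#' correlation exactly \eqn{\rho}.
#'
#' @param config a \code{\link{landscapeConfig}}.
#' @return A \linkS4class{PredictorStack} with one standardized layer per
#'   configured predictor (no nodata cells).
#' @export
generatePredictors <- function(config) {
  stopifnot(inherits(config, "landscapeConfig"))
  set.seed(config$seed)
  nr <- config$nRows; nc <- config$nCols
  Kr <- gaussSmoothMatrix(nr, config$autocorrRange)
  Kc <- gaussSmoothMatrix(nc, config$autocorrRange)
  fields <- lapply(seq_along(config$predictorNames), function(i) {
    standardizeField(Kr %*% matrix(rnorm(nr * nc), nr, nc) %*% t(Kc))
  })
  cp <- config$collinearPairs
  if (!is.null(cp) && nrow(cp)) {
    for (i in seq_len(nrow(cp))) {
      rho <- cp$rho[i]
      mixed <- rho * fields[[cp$source[i]]] +
        sqrt(1 - rho^2) * fields[[cp$target[i]]]
      fields[[cp$target[i]]] <- standardizeField(mixed)
    }
  }
  names(fields) <- config$predictorNames
  new("PredictorStack", layers = fields, xll = config$originLon,
      yll = config$originLat, cellSize = config$cellSize)
}

#' Niche specification
#'
#' A unimodal "true" niche: the product of independent Gaussian responses
#' over a few predictors, scaled by a baseline prevalence. Suitability at
#' optimum equals the baseline; it decays with squared distance from each
#' optimum in units of that predictor's tolerance.
#'
#' @param optima named numeric vector: optimum value per predictor (in the
#'   predictor's own, typically standardized, units).
#' @param tolerances named numeric vector of Gaussian widths (> 0), same
#'   names as \code{optima}.
#' @param weights named numeric vector of response weights (>= 0).
#' @param baseline maximum suitability, in (0, 1).
#' @return A list of class \code{"nicheSpec"}.
#' @export
nicheSpec <- function(optima = c(Bio6 = 0.3, Bio12 = 0.0, Bio4 = -0.4,
                                 Bio13 = 0.2),
                      tolerances = setNames(rep(0.4, length(optima)),
                                            names(optima)),
                      weights = setNames(
                        c(1, 0.9, 0.8, 0.6)[seq_along(optima)],
                        names(optima)),
                      baseline = 0.95) {
  if (any(tolerances <= 0)) stop("tolerances must be positive")
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (baseline <= 0 || baseline >= 1) stop("baseline must lie in (0, 1)")
  nm <- names(optima)
  if (is.null(nm)) stop("optima must be named by predictor")
  structure(list(optima = optima, tolerances = tolerances[nm],
                 weights = weights[nm], baseline = baseline),
            class = "nicheSpec")
}

#' True suitability surface of a niche over a landscape
#'
#' @param stack a \linkS4class{PredictorStack}.
#' @param niche a \code{\link{nicheSpec}}; every named predictor must be a
#'   layer of the stack.
#' @return A \linkS4class{RasterGrid} with values in (0, 1); the maximum
#'   (= baseline) is attained where all predictors sit at their optima.
#' @export
trueSuitability <- function(stack, niche) {
  stopifnot(inherits(niche, "nicheSpec"))
  missing <- setdiff(names(niche$optima), layerNames(stack))
  if (length(missing))
    stop("niche references missing layer(s): ", paste(missing, collapse = ", "))
  logs <- 0
  for (nm in names(niche$optima)) {
    x <- stack@layers[[nm]]
    logs <- logs - niche$weights[[nm]] *
      (x - niche$optima[[nm]])^2 / (2 * niche$tolerances[[nm]]^2)
  }
  rasterGrid(niche$baseline * exp(logs), stack@xll, stack@yll,
             stack@cellSize)
}

#' Sample occurrence points proportionally to true suitability
#'
#' Draws \code{n} distinct cells without replacement with probability
#' proportional to the suitability surface (optionally multiplied by a
#' sampling-bias raster) and returns their cell-center coordinates. Points
#' sit exactly at cell centers so extraction and thinning are exactly
#' reproducible.
#'
#' @param truth suitability \linkS4class{RasterGrid}.
#' @param n number of occurrences (default 131, the working presence count
#'   of the analysis this generator feeds).
#' @param bias optional \linkS4class{RasterGrid} of relative sampling effort.
#' @param seed integer RNG seed.
#' @param species species name written into the records.
#' @return A data.frame with columns species, longitude, latitude, source.
#' @export
sampleOccurrences <- function(truth, n = 131L, bias = NULL, seed = 1L,
                              species = "synthetic_sp") {
  w <- as.vector(truth@values)
  if (!is.null(bias)) {
    stopifnot(sameGeometry(truth, bias))
    w <- w * as.vector(bias@values)
  }
  land <- which(!is.na(w))
  if (n < 1) stop("n must be >= 1")
  if (n > length(land)) stop("n exceeds the number of land cells")
  set.seed(seed)
  picked <- land[sample.int(length(land), n, replace = FALSE,
                            prob = w[land])]
  rc <- arrayInd(picked, dim(truth@values))
  data.frame(species = species,
             longitude = cellLons(truth)[rc[, 2]],
             latitude = cellLats(truth)[rc[, 1]],
             source = "synthetic",
             stringsAsFactors = FALSE)
}

#' Generate rectangular protected-area polygons
#'
#' Places \code{nPolygons} axis-aligned rectangles at random positions and
#' aspect ratios, then bisects a common size-scale factor until the
#' rasterized union covers the requested fraction of the landscape to within
#' 10 percent relative. Returns polygons as closed lon/lat rings.
#'
#' @param config a \code{\link{landscapeConfig}} defining the landscape frame.
#' @param coverageFraction fraction of landscape area to cover, in [0, 1).
#' @param nPolygons number of rectangles.
#' @param seed integer RNG seed.
#' @return List of class \code{"polygonSet"}: each element a closed 2-column
#'   (lon, lat) ring matrix; attribute \code{coverage} holds the achieved
#'   rasterized fraction.
#' @export
generateProtectedAreas <- function(config, coverageFraction = 0.13,
                                   nPolygons = 8L, seed = 1L) {
  stopifnot(inherits(config, "landscapeConfig"))
  if (coverageFraction < 0 || coverageFraction >= 1)
    stop("coverageFraction must lie in [0, 1)")
  W <- config$nCols * config$cellSize
  H <- config$nRows * config$cellSize
  if (coverageFraction == 0)
    return(structure(list(), class = "polygonSet", coverage = 0))
  if (nPolygons < 1) stop("need at least one polygon for positive coverage")
  set.seed(seed)
  cx <- config$originLon + runif(nPolygons) * W
  cy <- config$originLat + runif(nPolygons) * H
  aspect <- exp(runif(nPolygons, log(0.5), log(2)))
  # unit dims so that at s = 1 each rectangle alone covers area/nPolygons
  base <- sqrt(W * H * coverageFraction / nPolygons)
  rings <- function(s) {
    lapply(seq_len(nPolygons), function(i) {
      w2 <- s * base * sqrt(aspect[i]) / 2
      h2 <- s * base / sqrt(aspect[i]) / 2
      x0 <- max(config$originLon, cx[i] - w2)
      x1 <- min(config$originLon + W, cx[i] + w2)
      y0 <- max(config$originLat, cy[i] - h2)
      y1 <- min(config$originLat + H, cy[i] + h2)
      cbind(lon = c(x0, x1, x1, x0, x0), lat = c(y0, y0, y1, y1, y0))
    })
  }
  template <- rasterGrid(matrix(0, config$nRows, config$nCols),
                         config$originLon, config$originLat,
                         config$cellSize)
  coverOf <- function(s) {
    m <- gridValues(rasterizePolygons(
      structure(rings(s), class = "polygonSet"), template))
    mean(m == 1)
  }
  lo <- 0; hi <- 1
  while (coverOf(hi) < coverageFraction && hi < 64) hi <- hi * 2
  if (coverOf(hi) < coverageFraction * 0.9)
    stop("requested coverage infeasible with ", nPolygons, " polygon(s)")
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    cv <- coverOf(mid)
    if (abs(cv - coverageFraction) <= 0.08 * coverageFraction) {
      lo <- hi <- mid; break
    }
    if (cv < coverageFraction) lo <- mid else hi <- mid
  }
  s <- (lo + hi) / 2
  structure(rings(s), class = "polygonSet", coverage = coverOf(s))
}
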