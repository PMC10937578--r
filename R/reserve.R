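# Systematic conservation planning: planning units aggregated from the
# suitability raster, a Marxan-style objective (cost + BLM * exposed
# boundary + SPF * shortfall penalty), simulated-annealing selection,
# repeat runs with selection frequency, and BLM calibration.

#' Planning-unit set
#'
#' Planning units aggregated from raster blocks, with per-unit cost,
#' conservation-feature amount (suitable-habitat area, km^2), status, and
#' shared boundary lengths between orthogonally adjacent units. Exterior
#' and non-shared edges are carried in each unit's perimeter so the exposed
#' boundary of any selection is computable.
#'
#' @slot units data.frame: id, blockRow, blockCol, cost, amount,
#'   landAreaKm2, perimeterKm, status (0 available, 2 locked-in,
#'   3 locked-out, Marxan coding).
#' @slot boundaries data.frame: id1, id2, lengthKm (symmetric, stored once
#'   with id1 < id2).
#' @slot cells list mapping unit position to linear raster cell indices
#'   (for rasterizing solutions).
#' @slot geometry list with the source grid geometry.
#'
#' @export
setClass("PlanningUnitSet",
  representation(units = "data.frame", boundaries = "data.frame",
                 cells = "list", geometry = "list"),
  validity = function(object) {
    msg <- character()
    u <- object@units
    if (anyDuplicated(u$id)) msg <- c(msg, "unit ids must be unique")
    if (any(u$amount < 0)) msg <- c(msg, "amounts must be >= 0")
    b <- object@boundaries
    if (nrow(b) && any(b$lengthKm < 0))
      msg <- c(msg, "boundary lengths must be >= 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "PlanningUnitSet", function(object) {
  u <- object@units
  cat(sprintf("PlanningUnitSet: %d units, %d adjacencies\n",
              nrow(u), nrow(object@boundaries)))
  cat(sprintf("  total amount %.1f km2, total cost %.1f, %d locked\n",
              sum(u$amount), sum(u$cost), sum(u$status != 0)))
})

#' @rdname PlanningUnitSet-class
#' @param x a \code{PlanningUnitSet}
#' @export
planningUnits <- function(x) x@units

#' @rdname PlanningUnitSet-class
#' @export
unitBoundaries <- function(x) x@boundaries

#' Aggregate a suitability raster into planning units
#'
#' Blocks of approximately \code{puSizeKm} x \code{puSizeKm} cells become
#' planning units; the feature amount is the summed suitable-cell area
#' within the unit (cell value times spherical cell area, so a binary map
#' gives suitable-habitat area). Blocks with no land cells are omitted.
#' Shared boundaries between orthogonal neighbours are the geodesic edge
#' lengths of the block interfaces.
#'
#' @param raster binary (or continuous) suitability
#'   \linkS4class{RasterGrid}.
#' @param puSizeKm nominal planning-unit size in km (default 10); must be
#'   at least one raster cell.
#' @param costMode \code{"area"} (default: cost = unit land area, standard
#'   practice) or \code{"habitat"} (cost = suitable-habitat amount within
#'   the unit).
#' @return A \linkS4class{PlanningUnitSet}.
#' @export
buildPlanningUnits <- function(raster, puSizeKm = 10,
                               costMode = c("area", "habitat")) {
  costMode <- match.arg(costMode)
  cellKm <- raster@cellSize * KM_PER_DEGREE
  f <- round(puSizeKm / cellKm)
  if (f < 1) stop("planning unit smaller than one raster cell")
  nr <- nRows(raster); nc <- nCols(raster)
  nbr <- ceiling(nr / f); nbc <- ceiling(nc / f)
  areas <- cellAreas(raster)
  v <- raster@values
  lats <- cellLats(raster)
  lons <- cellLons(raster)

  ids <- matrix(NA_integer_, nbr, nbc)
  rows <- list(); cells <- list(); nextId <- 0L
  for (bi in seq_len(nbr)) for (bj in seq_len(nbc)) {
    ri <- ((bi - 1) * f + 1):min(bi * f, nr)
    ci <- ((bj - 1) * f + 1):min(bj * f, nc)
    block <- v[ri, ci, drop = FALSE]
    land <- !is.na(block)
    if (!any(land)) next
    nextId <- nextId + 1L
    ids[bi, bj] <- nextId
    aRow <- areas[ri]
    landArea <- sum(land * aRow)
    amount <- sum(block[land] * (land * aRow)[land])
    hKm <- length(ri) * raster@cellSize * KM_PER_DEGREE
    wKm <- length(ci) * raster@cellSize * KM_PER_DEGREE *
      cos(mean(lats[ri]) * pi / 180)
    rows[[nextId]] <- data.frame(
      id = nextId, blockRow = bi, blockCol = bj, cost = NA_real_,
      amount = amount, landAreaKm2 = landArea,
      perimeterKm = 2 * (hKm + wKm), status = 0L)
    cellIdx <- as.vector(outer(ri, (ci - 1) * nr, "+"))
    cells[[nextId]] <- cellIdx
  }
  units <- do.call(rbind, rows)
  units$cost <- if (costMode == "area") units$landAreaKm2 else units$amount

  b1 <- integer(0); b2 <- integer(0); bl <- numeric(0)
  for (bi in seq_len(nbr)) for (bj in seq_len(nbc)) {
    id <- ids[bi, bj]
    if (is.na(id)) next
    if (bj < nbc && !is.na(ids[bi, bj + 1])) {   # east neighbour
      ri <- ((bi - 1) * f + 1):min(bi * f, nr)
      b1 <- c(b1, id); b2 <- c(b2, ids[bi, bj + 1])
      bl <- c(bl, length(ri) * raster@cellSize * KM_PER_DEGREE)
    }
    if (bi < nbr && !is.na(ids[bi + 1, bj])) {   # south neighbour
      ci <- ((bj - 1) * f + 1):min(bj * f, nc)
      latEdge <- lats[min(bi * f, nr)] - raster@cellSize / 2
      b1 <- c(b1, id); b2 <- c(b2, ids[bi + 1, bj])
      bl <- c(bl, length(ci) * raster@cellSize * KM_PER_DEGREE *
                cos(latEdge * pi / 180))
    }
  }
  new("PlanningUnitSet", units = units,
      boundaries = data.frame(id1 = b1, id2 = b2, lengthKm = bl),
      cells = cells,
      geometry = list(xll = raster@xll, yll = raster@yll,
                      cellSize = raster@cellSize, nRows = nr, nCols = nc))
}

#' Reserve-selection configuration
#'
#' @param targetFraction representation target as a fraction of the total
#'   feature amount (default 0.30).
#' @param blm boundary length modifier (default 100).
#' @param spf species penalty factor (> 0, default 10).
#' @param iterations simulated-annealing flips per run (default 1e6;
#'   reduce for small instances).
#' @param runs repeat runs for selection frequency (default 50).
#' @param coolingFinal final temperature as a fraction of the initial
#'   (default 1e-4, geometric schedule).
#' @param seed integer RNG seed.
#' @return List of class \code{"reserveConfig"}.
#' @export
reserveConfig <- function(targetFraction = 0.30, blm = 100, spf = 10,
                          iterations = 1e6, runs = 50L,
                          coolingFinal = 1e-4, seed = 1L) {
  if (targetFraction <= 0 || targetFraction >= 1)
    stop("targetFraction must lie in (0, 1)")
  if (blm < 0) stop("blm must be >= 0")
  if (spf <= 0) stop("spf must be > 0")
  structure(list(targetFraction = targetFraction, blm = blm, spf = spf,
                 iterations = as.integer(iterations), runs = as.integer(runs),
                 coolingFinal = coolingFinal, seed = as.integer(seed)),
            class = "reserveConfig")
}

# Cost of a greedy target-completing set (cheapest cost-per-amount first);
# the base cost of the shortfall penalty.
greedyPenaltyCost <- function(puSet, target) {
  u <- puSet@units
  ord <- order(u$cost / pmax(u$amount, 1e-12))
  held <- 0; cost <- 0
  for (i in ord) {
    if (held >= target) break
    if (u$amount[i] <= 0) next
    held <- held + u$amount[i]; cost <- cost + u$cost[i]
  }
  cost
}

# Internal: neighbor index/length lists keyed by unit position.
neighborLists <- function(puSet) {
  n <- nrow(puSet@units)
  nb <- vector("list", n); ln <- vector("list", n)
  b <- puSet@boundaries
  pos <- match(c(b$id1, b$id2), puSet@units$id)
  i1 <- pos[seq_len(nrow(b))]; i2 <- pos[-seq_len(nrow(b))]
  for (k in seq_len(nrow(b))) {
    nb[[i1[k]]] <- c(nb[[i1[k]]], i2[k]); ln[[i1[k]]] <- c(ln[[i1[k]]], b$lengthKm[k])
    nb[[i2[k]]] <- c(nb[[i2[k]]], i1[k]); ln[[i2[k]]] <- c(ln[[i2[k]]], b$lengthKm[k])
  }
  list(nb = nb, len = ln)
}

#' Reserve objective with decomposition
#'
#' \eqn{\sum_{selected} cost + BLM \times} exposed boundary (shared edges
#' with unselected units plus exterior edges) \eqn{+ SPF \times
#' (shortfall/target) \times} greedy-completion base cost.
#'
#' @param selection vector of selected unit ids.
#' @param puSet a \linkS4class{PlanningUnitSet}.
#' @param config a \code{\link{reserveConfig}}.
#' @return List: \code{objective}, \code{cost}, \code{boundaryKm},
#'   \code{penalty}, \code{amountHeld}, \code{target}, \code{shortfall}.
#' @export
reserveObjective <- function(selection, puSet, config) {
  u <- puSet@units
  if (length(selection) && !all(selection %in% u$id))
    stop("unknown unit id(s) in selection")
  selPos <- match(selection, u$id)
  inSel <- rep(FALSE, nrow(u)); inSel[selPos] <- TRUE
  cost <- sum(u$cost[inSel])
  b <- puSet@boundaries
  bothSel <- if (nrow(b))
    inSel[match(b$id1, u$id)] & inSel[match(b$id2, u$id)] else logical(0)
  boundary <- sum(u$perimeterKm[inSel]) - 2 * sum(b$lengthKm[bothSel])
  target <- config$targetFraction * sum(u$amount)
  held <- sum(u$amount[inSel])
  shortfall <- max(0, target - held)
  base <- greedyPenaltyCost(puSet, target)
  penalty <- if (target > 0) config$spf * (shortfall / target) * base else 0
  list(objective = cost + config$blm * boundary + penalty, cost = cost,
       boundaryKm = boundary, penalty = penalty, amountHeld = held,
       target = target, shortfall = shortfall)
}

#' Simulated-annealing reserve selection (single run)
#'
#' Starts from a random feasible-status selection, proposes single-unit
#' flips, accepts improvements always and worsenings with probability
#' \eqn{e^{-\Delta/T}}; the temperature starts at the mean absolute delta
#' of 100 random probe flips and decays geometrically to
#' \code{coolingFinal} of that over the configured iterations. Locked-in /
#' locked-out statuses are respected; the best-seen selection is returned.
#'
#' @param puSet a \linkS4class{PlanningUnitSet}.
#' @param config a \code{\link{reserveConfig}}.
#' @param seed optional seed overriding \code{config$seed}.
#' @return List of class \code{"reserveSolution"}: \code{selected} (ids),
#'   objective decomposition (recomputed from the selection), and run
#'   metadata.
#' @export
annealReserve <- function(puSet, config, seed = NULL) {
  u <- puSet@units
  n <- nrow(u)
  target <- config$targetFraction * sum(u$amount)
  if (sum(u$amount[u$status != 3L]) < target)
    stop(sprintf(
      "infeasible target: %.2f available of %.2f required",
      sum(u$amount[u$status != 3L]), target))
  base <- greedyPenaltyCost(puSet, target)
  nl <- neighborLists(puSet)
  set.seed(if (is.null(seed)) config$seed else seed)

  flippable <- which(u$status == 0L)
  sel <- u$status == 2L
  sel[flippable] <- runif(length(flippable)) < 0.5
  cost <- sum(u$cost[sel])
  held <- sum(u$amount[sel])
  boundary <- 0
  for (i in which(sel)) {
    sharedSel <- if (length(nl$nb[[i]]))
      sum(nl$len[[i]][sel[nl$nb[[i]]]]) else 0
    boundary <- boundary + u$perimeterKm[i] - sharedSel
  }
  penaltyOf <- function(h) if (target > 0)
    config$spf * max(0, target - h) / target * base else 0
  obj <- cost + config$blm * boundary + penaltyOf(held)

  deltaOf <- function(i) {
    sgn <- if (sel[i]) -1 else 1
    sharedSel <- if (length(nl$nb[[i]]))
      sum(nl$len[[i]][sel[nl$nb[[i]]]]) else 0
    dBound <- sgn * (u$perimeterKm[i] - 2 * sharedSel)
    dPen <- penaltyOf(held + sgn * u$amount[i]) - penaltyOf(held)
    sgn * u$cost[i] + config$blm * dBound + dPen
  }
  # initial temperature from random probe flips
  probes <- sample(flippable, min(100, length(flippable)), replace = TRUE)
  T0 <- mean(abs(vapply(probes, deltaOf, numeric(1))))
  if (!is.finite(T0) || T0 <= 0) T0 <- 1
  decay <- config$coolingFinal^(1 / max(1, config$iterations))

  best <- sel; bestObj <- obj
  Temp <- T0
  picks <- sample(flippable, config$iterations, replace = TRUE)
  us <- runif(config$iterations)
  for (it in seq_len(config$iterations)) {
    i <- picks[it]
    d <- deltaOf(i)
    if (d < 0 || us[it] < exp(-d / Temp)) {
      sgn <- if (sel[i]) -1 else 1
      sel[i] <- !sel[i]
      cost <- cost + sgn * u$cost[i]
      held <- held + sgn * u$amount[i]
      obj <- obj + d
      if (obj < bestObj) { bestObj <- obj; best <- sel }
    }
    Temp <- Temp * decay
  }
  dec <- reserveObjective(u$id[best], puSet, config)
  structure(list(selected = u$id[best], objective = dec$objective,
                 cost = dec$cost, boundaryKm = dec$boundaryKm,
                 penalty = dec$penalty, amountHeld = dec$amountHeld,
                 target = dec$target, shortfall = dec$shortfall,
                 config = config),
            class = "reserveSolution")
}

#' @export
print.reserveSolution <- function(x, ...) {
  cat(sprintf("reserveSolution: %d units, objective %.2f\n",
              length(x$selected), x$objective))
  cat(sprintf("  cost %.2f + BLM*boundary %.2f + penalty %.2f; held %.1f / target %.1f km2\n",
              x$cost, x$config$blm * x$boundaryKm, x$penalty,
              x$amountHeld, x$target))
  invisible(x)
}

#' Repeated annealing runs with selection frequency
#'
#' Independent runs under per-run seeds; the best (lowest-objective) run is
#' the priority solution and the per-unit selection frequency across runs
#' measures irreplaceability.
#'
#' @param puSet a \linkS4class{PlanningUnitSet}.
#' @param config a \code{\link{reserveConfig}} (\code{runs} controls the
#'   count).
#' @return The best \code{reserveSolution} augmented with
#'   \code{selectionFrequency} (named by unit id) and \code{bestRun}.
#' @export
repeatRuns <- function(puSet, config) {
  if (config$runs < 1) stop("need at least one run")
  freq <- setNames(numeric(nrow(puSet@units)), puSet@units$id)
  best <- NULL; bestRun <- NA_integer_
  for (r in seq_len(config$runs)) {
    sol <- annealReserve(puSet, config, seed = config$seed + r)
    freq[as.character(sol$selected)] <-
      freq[as.character(sol$selected)] + 1
    if (is.null(best) || sol$objective < best$objective) {
      best <- sol; bestRun <- r
    }
  }
  best$selectionFrequency <- freq / config$runs
  best$bestRun <- bestRun
  best
}

#' BLM calibration table
#'
#' Re-solves the instance over a ladder of boundary-length-modifier values
#' and reports the median best cost and boundary per BLM, exposing the
#' compactness/cost trade-off.
#'
#' @param puSet a \linkS4class{PlanningUnitSet}.
#' @param blms numeric vector of BLM values.
#' @param config base \code{\link{reserveConfig}}.
#' @param runsPerBlm annealing runs per BLM value (default 5, medians
#'   reported).
#' @return data.frame: blm, objective, cost, boundaryKm, penalty (medians).
#' @export
blmCalibration <- function(puSet, blms, config = reserveConfig(),
                           runsPerBlm = 5L) {
  rows <- lapply(blms, function(b) {
    cfg <- config; cfg$blm <- b
    sols <- lapply(seq_len(runsPerBlm), function(r)
      annealReserve(puSet, cfg, seed = cfg$seed + 1000 * r))
    data.frame(blm = b,
               objective = stats::median(vapply(sols, `[[`, numeric(1),
                                                "objective")),
               cost = stats::median(vapply(sols, `[[`, numeric(1), "cost")),
               boundaryKm = stats::median(vapply(sols, `[[`, numeric(1),
                                                 "boundaryKm")),
               penalty = stats::median(vapply(sols, `[[`, numeric(1),
                                              "penalty")))
  })
  do.call(rbind, rows)
}

#' Rasterize a reserve solution
#'
#' @param puSet a \linkS4class{PlanningUnitSet}.
#' @param solution a \code{reserveSolution} (or vector of unit ids).
#' @return Binary \linkS4class{RasterGrid}: 1 inside selected units.
#' @export
solutionRaster <- function(puSet, solution) {
  ids <- if (inherits(solution, "reserveSolution")) solution$selected
         else solution
  g <- puSet@geometry
  m <- matrix(0, g$nRows, g$nCols)
  for (id in ids) m[puSet@cells[[match(id, puSet@units$id)]]] <- 1
  rasterGrid(m, g$xll, g$yll, g$cellSize)
}

#' Write / read Marxan-format input files
#'
#' Standard tab-separated Marxan tables: \code{pu.dat} (id, cost, status),
#' \code{spec.dat} (id, target, spf, name), \code{puvspr.dat} (species, pu,
#' amount), \code{bound.dat} (id1, id2, boundary).
#'
#' @param puSet a \linkS4class{PlanningUnitSet}.
#' @param dir output directory.
#' @param config a \code{\link{reserveConfig}} supplying target and spf.
#' @param species feature name (default \code{"habitat"}).
#' @return Invisibly, the written paths. \code{readMarxanFiles} returns a
#'   list of the four tables.
#' @export
writeMarxanFiles <- function(puSet, dir, config = reserveConfig(),
                             species = "habitat") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  u <- puSet@units
  tw <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  tw(data.frame(id = u$id, cost = u$cost, status = u$status), "pu.dat")
  tw(data.frame(id = 1L,
                target = config$targetFraction * sum(u$amount),
                spf = config$spf, name = species), "spec.dat")
  tw(data.frame(species = 1L, pu = u$id, amount = u$amount), "puvspr.dat")
  tw(data.frame(id1 = puSet@boundaries$id1, id2 = puSet@boundaries$id2,
                boundary = puSet@boundaries$lengthKm), "bound.dat")
  invisible(file.path(dir, c("pu.dat", "spec.dat", "puvspr.dat",
                             "bound.dat")))
}

#' @rdname writeMarxanFiles
#' @export
readMarxanFiles <- function(dir) {
  rd <- function(f) utils::read.table(file.path(dir, f), header = TRUE,
                                      sep = "\t")
  list(pu = rd("pu.dat"), spec = rd("spec.dat"),
       puvspr = rd("puvspr.dat"), bound = rd("bound.dat"))
}
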