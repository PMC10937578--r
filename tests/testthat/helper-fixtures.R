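# Shared fixtures: tiny landscapes, value tables and planning-unit toys,
# all built in code at test time.

smallLandscape <- function(seed = 3L, nRows = 60L, nCols = 60L) {
  cfg <- landscapeConfig(nRows = nRows, nCols = nCols, seed = seed)
  list(config = cfg, stack = generatePredictors(cfg))
}

nicheVars <- c("Bio6", "Bio12", "Bio4", "Bio13")

defaultNiche <- function() nicheSpec()

# deterministic little raster with a few NA cells
toyRaster <- function(nr = 6, nc = 5, seed = 1, xll = 100, yll = 30,
                      cellSize = 0.5, withNA = TRUE) {
  set.seed(seed)
  m <- matrix(runif(nr * nc), nr, nc)
  if (withNA) m[cbind(c(1, nr), c(1, nc))] <- NA
  rasterGrid(m, xll, yll, cellSize)
}

# hand-buildable planning-unit set (units in a row, unit-square footprints)
handPuSet <- function(cost, amount, perimeter = rep(4, length(cost)),
                      sharedLen = 1) {
  n <- length(cost)
  units <- data.frame(id = seq_len(n), blockRow = 1L, blockCol = seq_len(n),
                      cost = cost, amount = amount, landAreaKm2 = 1,
                      perimeterKm = perimeter, status = 0L)
  boundaries <- if (n >= 2)
    data.frame(id1 = seq_len(n - 1), id2 = 2:n,
               lengthKm = rep(sharedLen, n - 1))
  else data.frame(id1 = integer(), id2 = integer(), lengthKm = numeric())
  new("PlanningUnitSet", units = units, boundaries = boundaries,
      cells = list(), geometry = list())
}

# exhaustive optimum of the reserve objective over all selections
enumerateOptimum <- function(puSet, config) {
  ids <- puSet@units$id
  n <- length(ids)
  best <- Inf; bestSel <- integer(0)
  for (mask in 0:(2^n - 1)) {
    sel <- ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    ob <- reserveObjective(sel, puSet, config)$objective
    if (ob < best) { best <- ob; bestSel <- sel }
  }
  list(objective = best, selected = bestSel)
}
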