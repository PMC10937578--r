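test_that("predictor generation is deterministic and standardized", {
  cfg <- landscapeConfig(nRows = 40, nCols = 40, seed = 11)
  s1 <- generatePredictors(cfg)
  s2 <- generatePredictors(cfg)
  expect_identical(s1@layers, s2@layers)
  for (nm in layerNames(s1)) {
    v <- as.vector(s1@layers[[nm]])
    expect_equal(mean(v), 0, tolerance = 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-10)
  }
})

test_that("collinear pairs hit their target correlation", {
  # perfect-copy case: rho = 1 gives identical standardized layers
  cfg1 <- landscapeConfig(nRows = 40, nCols = 40,
                          predictorNames = c("a", "b"),
                          collinearPairs = data.frame(source = 1L,
                                                      target = 2L, rho = 1),
                          seed = 2)
  st1 <- generatePredictors(cfg1)
  expect_equal(st1@layers[["a"]], st1@layers[["b"]], tolerance = 1e-12)

  # rho = 0.9 on a 100x100 grid: empirical r within [0.85, 0.95]
  # (oracle: direct Pearson correlation over all 10^4 cells)
  cfg2 <- landscapeConfig(nRows = 100, nCols = 100,
                          predictorNames = c("a", "b"),
                          collinearPairs = data.frame(source = 1L,
                                                      target = 2L,
                                                      rho = 0.9),
                          seed = 7)
  st2 <- generatePredictors(cfg2)
  r <- cor(as.vector(st2@layers[["a"]]), as.vector(st2@layers[["b"]]))
  expect_gt(r, 0.85); expect_lt(r, 0.95)

  # both default pairs, several seeds (|r - rho| <= 0.05 property)
  for (seed in 1:3) {
    st <- generatePredictors(landscapeConfig(seed = seed))
    v <- stackValues(st)
    expect_lt(abs(cor(v[, "Bio4"], v[, "Bio1"]) - 0.85), 0.05)
    expect_lt(abs(cor(v[, "Bio6"], v[, "Bio11"]) - 0.9), 0.05)
  }
})

test_that("default landscape carries enough predictors for screening", {
  st <- generatePredictors(landscapeConfig(nRows = 20, nCols = 20))
  expect_gte(nLayers(st), 12)
  expect_true(all(c("Bio3", "Bio4", "Bio5", "Bio6", "Bio8", "Bio12",
                    "Bio13", "slope", "T_bs", "T_esp", "T_cec_soil",
                    "T_cec_clay") %in% layerNames(st)))
})

test_that("config invariants are enforced", {
  expect_error(landscapeConfig(nRows = 4), "nRows")
  expect_error(landscapeConfig(autocorrRange = 0), "autocorrRange")
  expect_error(landscapeConfig(collinearPairs = data.frame(
    source = 1L, target = 2L, rho = 1.2)), "\\[-1, 1\\]")
})

test_that("true suitability peaks at the configured optima", {
  ls <- smallLandscape(seed = 5, nRows = 30, nCols = 30)
  st <- ls$stack

  # single predictor, optimum 0: suitability maximal where |predictor|
  # is smallest
  n1 <- nicheSpec(optima = c(Bio6 = 0), tolerances = c(Bio6 = 1),
                  weights = c(Bio6 = 1))
  s1 <- trueSuitability(st, n1)
  expect_equal(which.max(gridValues(s1)),
               which.min(abs(st@layers[["Bio6"]])))

  # two predictors: argmax equals the cell minimizing the weighted squared
  # distance to the optima (exhaustive scan oracle)
  n2 <- nicheSpec(optima = c(Bio6 = 0.5, Bio12 = -0.5),
                  tolerances = c(Bio6 = 0.7, Bio12 = 0.5),
                  weights = c(Bio6 = 1, Bio12 = 2))
  s2 <- trueSuitability(st, n2)
  d <- 1 * (st@layers[["Bio6"]] - 0.5)^2 / (2 * 0.7^2) +
       2 * (st@layers[["Bio12"]] + 0.5)^2 / (2 * 0.5^2)
  expect_equal(which.max(gridValues(s2)), which.min(d))

  # degenerate niche: zero weights give the constant baseline
  n3 <- nicheSpec(optima = c(Bio6 = 0), tolerances = c(Bio6 = 1),
                  weights = c(Bio6 = 0), baseline = 0.5)
  expect_true(all(gridValues(trueSuitability(st, n3)) == 0.5))

  expect_error(trueSuitability(st, nicheSpec(optima = c(nope = 0),
                                             tolerances = c(nope = 1),
                                             weights = c(nope = 1))),
               "missing layer")
})

test_that("occurrence sampling respects the suitability support", {
  tmpl <- getLayer(smallLandscape(seed = 2, nRows = 10, nCols = 10)$stack,
                   "Bio6")
  lons <- tmpl@xll + (seq_len(10) - 0.5) * tmpl@cellSize
  lats <- tmpl@yll + (10 - seq_len(10) + 0.5) * tmpl@cellSize

  # constant truth, n = all cells: every cell sampled exactly once
  cst <- rasterGrid(matrix(0.5, 10, 10), tmpl@xll, tmpl@yll, tmpl@cellSize)
  occ <- sampleOccurrences(cst, n = 100, seed = 4)
  expect_equal(nrow(unique(occ[, c("longitude", "latitude")])), 100)

  # truth zero except 5 cells: exactly those cells returned
  z <- matrix(0, 10, 10)
  picks <- c(3L, 17L, 55L, 70L, 99L)
  z[picks] <- 1
  zr <- rasterGrid(z, tmpl@xll, tmpl@yll, tmpl@cellSize)
  occ5 <- sampleOccurrences(zr, n = 5, seed = 9)
  got <- (match(occ5$longitude, lons) - 1) * 10 +
    match(occ5$latitude, lats)
  expect_equal(sort(got), sort(picks))

  # default n = 131 on the default landscape; reproducible under a seed
  big <- smallLandscape(seed = 1)
  truth <- trueSuitability(big$stack, defaultNiche())
  o1 <- sampleOccurrences(truth, seed = 12)
  o2 <- sampleOccurrences(truth, seed = 12)
  expect_equal(nrow(o1), 131)
  expect_identical(o1, o2)

  expect_error(sampleOccurrences(cst, n = 101, seed = 1), "exceeds")
})

test_that("per-cell sampling frequency tracks the truth probabilities", {
  ls <- smallLandscape(seed = 6, nRows = 20, nCols = 20)
  truth <- trueSuitability(ls$stack, defaultNiche())
  counts <- numeric(400)
  lons <- truth@xll + (seq_len(20) - 0.5) * truth@cellSize
  lats <- truth@yll + (20 - seq_len(20) + 0.5) * truth@cellSize
  for (d in 1:200) {
    occ <- sampleOccurrences(truth, n = 50, seed = 1000 + d)
    idx <- (match(occ$longitude, lons) - 1) * 20 + match(occ$latitude, lats)
    counts[idx] <- counts[idx] + 1
  }
  expect_gt(cor(counts / 200, as.vector(gridValues(truth))), 0.9)
})

test_that("protected-area generation hits the coverage band", {
  cfg <- landscapeConfig(nRows = 50, nCols = 50, seed = 8)

  expect_length(generateProtectedAreas(cfg, 0), 0)

  pa <- generateProtectedAreas(cfg, 0.2, nPolygons = 5, seed = 3)
  tmpl <- rasterGrid(matrix(0, 50, 50), cfg$originLon, cfg$originLat,
                     cfg$cellSize)
  cover <- mean(gridValues(rasterizePolygons(pa, tmpl)) == 1)
  expect_gte(cover, 0.18); expect_lte(cover, 0.22)

  # near-saturation with a single polygon
  pa99 <- generateProtectedAreas(cfg, 0.95, nPolygons = 1, seed = 3)
  cover99 <- mean(gridValues(rasterizePolygons(pa99, tmpl)) == 1)
  expect_gt(cover99, 0.85)

  expect_error(generateProtectedAreas(cfg, 1.0, 3), "coverageFraction")
})
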