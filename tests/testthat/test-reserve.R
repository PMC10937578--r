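test_that("planning units aggregate the raster by blocks", {
  # uniform binary-1 raster on an equal-ish area toy grid: every unit's
  # amount equals its land area
  r <- rasterGrid(matrix(1, 8, 8), 100, 0, 0.09)  # ~10 km cells at equator
  pu <- buildPlanningUnits(r, puSizeKm = 20)       # 2x2-cell units
  u <- planningUnits(pu)
  expect_equal(nrow(u), 16)
  expect_equal(u$amount, u$landAreaKm2, tolerance = 1e-12)
  expect_equal(u$cost, u$landAreaKm2, tolerance = 1e-12)

  # single suitable cell: exactly one unit has positive amount
  m <- matrix(0, 8, 8); m[3, 5] <- 1
  pu1 <- buildPlanningUnits(rasterGrid(m, 100, 0, 0.09), puSizeKm = 20)
  expect_equal(sum(planningUnits(pu1)$amount > 0), 1)

  # random raster: unit amounts equal brute-force per-cell accumulation
  set.seed(31)
  vals <- matrix(rbinom(64, 1, 0.5), 8, 8)
  r3 <- rasterGrid(vals, 100, 30, 0.09)
  pu3 <- buildPlanningUnits(r3, puSizeKm = 20)
  areas <- cellAreas(r3)
  for (k in seq_len(nrow(planningUnits(pu3)))) {
    row <- planningUnits(pu3)[k, ]
    ri <- ((row$blockRow - 1) * 2 + 1):(row$blockRow * 2)
    ci <- ((row$blockCol - 1) * 2 + 1):(row$blockCol * 2)
    expect_equal(row$amount,
                 sum(vals[ri, ci] * matrix(areas[ri], 2, 2)),
                 tolerance = 1e-9)
  }

  # habitat cost mode reproduces the amount-as-cost definition
  puH <- buildPlanningUnits(r3, puSizeKm = 20, costMode = "habitat")
  expect_equal(planningUnits(puH)$cost, planningUnits(puH)$amount)
  expect_error(buildPlanningUnits(r3, puSizeKm = 1), "smaller")
})

test_that("the objective decomposition matches hand arithmetic on a 6-unit toy", {
  pu <- handPuSet(cost = c(3, 1, 4, 1, 5, 9),
                  amount = c(2, 2, 1, 0, 3, 1))
  cfg <- reserveConfig(targetFraction = 0.3, blm = 2, spf = 10)
  # target = 0.3 * 9 = 2.7; greedy completion: unit 2 (0.5/km2) then
  # unit 1 -> base cost 4
  # selection {2}: cost 1, boundary 4, shortfall 0.7
  o1 <- reserveObjective(2, pu, cfg)
  expect_equal(o1$cost, 1)
  expect_equal(o1$boundaryKm, 4)
  expect_equal(o1$penalty, 10 * (0.7 / 2.7) * 4, tolerance = 1e-12)
  expect_equal(o1$objective, 1 + 2 * 4 + 10 * (0.7 / 2.7) * 4,
               tolerance = 1e-12)
  # selection {1,2}: adjacent, shared edge 1 -> boundary 8 - 2 = 6
  o2 <- reserveObjective(c(1, 2), pu, cfg)
  expect_equal(o2$cost, 4)
  expect_equal(o2$boundaryKm, 6)
  expect_equal(o2$penalty, 0)
  # selection {1,3,5}: no adjacency among them -> boundary 12
  o3 <- reserveObjective(c(1, 3, 5), pu, cfg)
  expect_equal(o3$boundaryKm, 12)
  expect_equal(o3$cost, 12)
  expect_equal(o3$penalty, 0)

  # empty selection with tiny SPF contributes (almost) only penalty
  o0 <- reserveObjective(integer(0), pu, cfg)
  expect_equal(o0$cost, 0)
  expect_equal(o0$boundaryKm, 0)
  expect_error(reserveObjective(99, pu, cfg), "unknown unit")
})

test_that("annealing matches the exhaustive optimum on a 12-unit instance", {
  set.seed(32)
  vals <- matrix(rbinom(48, 1, 0.6) * runif(48, 0.5, 1), 8, 6)
  r <- rasterGrid(vals, 105, 25, 0.09)
  pu <- buildPlanningUnits(binarize(r, 0.24), puSizeKm = 20)
  expect_lte(nrow(planningUnits(pu)), 12)
  cfg <- reserveConfig(targetFraction = 0.3, blm = 5, spf = 10,
                       iterations = 50000, runs = 1, seed = 1)
  exact <- enumerateOptimum(pu, cfg)
  wins <- 0
  for (s in 1:10) {
    sol <- annealReserve(pu, cfg, seed = s)
    if (abs(sol$objective - exact$objective) < 1e-6) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("solutions always recompute their decomposition and respect locks", {
  set.seed(33)
  vals <- matrix(rbinom(64, 1, 0.5), 8, 8)
  r <- rasterGrid(vals, 100, 20, 0.09)
  pu <- buildPlanningUnits(r, puSizeKm = 20)
  cfg <- reserveConfig(targetFraction = 0.3, blm = 10, spf = 10,
                       iterations = 20000, runs = 1, seed = 2)
  sol <- annealReserve(pu, cfg)
  dec <- reserveObjective(sol$selected, pu, cfg)
  expect_equal(sol$objective, dec$objective, tolerance = 1e-9)
  expect_equal(sol$cost + cfg$blm * sol$boundaryKm + sol$penalty,
               sol$objective, tolerance = 1e-9)

  # a unit holding the entire feature with huge SPF is always selected
  puF <- handPuSet(cost = c(1, 1, 1), amount = c(5, 0, 0))
  cfgF <- reserveConfig(targetFraction = 0.5, blm = 0, spf = 1e6,
                        iterations = 5000, seed = 3)
  solF <- annealReserve(puF, cfgF)
  expect_true(1 %in% solF$selected)

  # locked-out units never enter; infeasible targets are rejected
  puL <- handPuSet(cost = c(1, 1), amount = c(3, 3))
  puL@units$status <- c(0L, 3L)
  solL <- annealReserve(puL, reserveConfig(targetFraction = 0.4, blm = 0,
                                           spf = 100, iterations = 2000,
                                           seed = 1))
  expect_false(2 %in% solL$selected)
  puBad <- handPuSet(cost = c(1, 1), amount = c(1, 1))
  puBad@units$status <- c(3L, 3L)
  expect_error(annealReserve(puBad, reserveConfig(targetFraction = 0.9)),
               "infeasible")
})

test_that("repeat runs report selection frequencies and the best solution", {
  puF <- handPuSet(cost = c(1, 4, 4, 4), amount = c(6, 1, 1, 1))
  cfg <- reserveConfig(targetFraction = 0.6, blm = 0, spf = 1000,
                       iterations = 3000, runs = 20, seed = 5)
  sol <- repeatRuns(puF, cfg)
  # unit 1 is required by every target-meeting solution (amount 6 of 9,
  # target 5.4 > 3 available without it)
  expect_equal(unname(sol$selectionFrequency["1"]), 1.0)
  expect_true(all(sol$selectionFrequency >= 0 &
                  sol$selectionFrequency <= 1))
  one <- repeatRuns(puF, reserveConfig(targetFraction = 0.6, blm = 0,
                                       spf = 1000, iterations = 2000,
                                       runs = 1, seed = 6))
  expect_true(all(one$selectionFrequency %in% c(0, 1)))
})

test_that("larger BLM buys compactness on a toy trade-off", {
  # units in a row; selecting two adjacent cheap units vs one distant unit
  pu <- handPuSet(cost = c(2, 2, 100, 2.5), amount = c(2, 2, 0, 4))
  cfgs <- reserveConfig(targetFraction = 0.49, spf = 1000,
                        iterations = 20000, seed = 7)
  tab <- blmCalibration(pu, blms = c(0, 50), config = cfgs,
                        runsPerBlm = 3)
  expect_equal(nrow(tab), 2)
  expect_lte(tab$boundaryKm[2], tab$boundaryKm[1] + 1e-9)
  single <- blmCalibration(pu, blms = 10, config = cfgs, runsPerBlm = 2)
  expect_equal(nrow(single), 1)
})

test_that("Marxan-format files round-trip", {
  set.seed(34)
  vals <- matrix(rbinom(64, 1, 0.5), 8, 8)
  pu <- buildPlanningUnits(rasterGrid(vals, 100, 20, 0.09), puSizeKm = 20)
  d <- withr::local_tempdir()
  writeMarxanFiles(pu, d, reserveConfig(targetFraction = 0.3, spf = 10))
  got <- readMarxanFiles(d)
  expect_equal(got$pu$id, planningUnits(pu)$id)
  expect_equal(got$pu$cost, planningUnits(pu)$cost, tolerance = 1e-6)
  expect_equal(got$puvspr$amount, planningUnits(pu)$amount,
               tolerance = 1e-6)
  expect_equal(nrow(got$bound), nrow(unitBoundaries(pu)))
  expect_equal(got$spec$target,
               0.3 * sum(planningUnits(pu)$amount), tolerance = 1e-6)
})

test_that("solution rasters mark exactly the selected units", {
  m <- matrix(1, 4, 4)
  pu <- buildPlanningUnits(rasterGrid(m, 100, 20, 0.09), puSizeKm = 20)
  sol <- list(selected = c(1L, 4L))
  class(sol) <- "reserveSolution"
  mask <- solutionRaster(pu, sol)
  expect_equal(sum(gridValues(mask)), 8)  # two 2x2 units
})
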