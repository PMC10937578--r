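test_that("background sampling saturates, is uniform-without-replacement and reproducible", {
  ls <- smallLandscape(seed = 2, nRows = 10, nCols = 10)
  st <- ls$stack
  # saturation: request more than available -> all land cells
  bg <- sampleBackground(st, 10000, seed = 1)
  expect_equal(sort(bg$cells), which(landMask(st)))
  # determinism: same seed -> identical sorted index sets
  b1 <- sampleBackground(st, 40, seed = 9)
  b2 <- sampleBackground(st, 40, seed = 9)
  expect_identical(sort(b1$cells), sort(b2$cells))
  expect_equal(length(b1$cells), 40)
  expect_equal(formals(sampleBackground)$n, 10000L)
})

test_that("feature expansion produces the documented counts and ranges", {
  set.seed(3)
  pres <- matrix(rnorm(10 * 12), 10, 12,
                 dimnames = list(NULL, paste0("v", 1:12)))
  bg <- matrix(rnorm(50 * 12), 50, 12,
               dimnames = list(NULL, paste0("v", 1:12)))
  feL <- buildFeatures(pres, bg, "L")
  expect_equal(nrow(feL$defs), 12)           # FC = L: one per variable
  feLQ <- buildFeatures(pres, bg, "LQ")
  expect_equal(nrow(feLQ$defs), 24)          # FC = LQ: 2v
  feH <- buildFeatures(pres, bg, "H", nKnots = 7)
  expect_equal(nrow(feH$defs), 12 * 7)
  expect_true(all(feLQ$Fpres >= 0 & feLQ$Fpres <= 1))
  expect_true(all(feH$Fbg >= 0 & feH$Fbg <= 1))
  # hinge knots strictly inside the variable range
  hd <- feH$defs
  expect_true(all(hd$knot > feH$scaling$lo[hd$var1] &
                  hd$knot < feH$scaling$hi[hd$var1]))
  # constant variable: Q/H/T skipped with a warning
  presC <- cbind(pres, cst = 1); bgC <- cbind(bg, cst = 1)
  expect_warning(feC <- buildFeatures(presC, bgC, "LQH"), "constant")
  expect_false(any(feC$defs$var1 == "cst" & feC$defs$class != "L"))
  expect_error(buildFeatures(pres, bg, "XYZ"), "LQHPT")
})

test_that("total shrinkage at huge RM gives the uniform null model", {
  set.seed(4)
  pres <- matrix(rnorm(8 * 2), 8, 2, dimnames = list(NULL, c("a", "b")))
  bg <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("a", "b")))
  fe <- buildFeatures(pres, bg, "LQ")
  mod <- fitMaxent(fe, rm = 1e6)
  expect_true(all(mod@lambda == 0))
  N <- mod@meta$nNorm
  raw <- predictRaw(mod, rbind(bg, pres))
  expect_equal(raw, rep(1 / N, N), tolerance = 1e-12)
  # null logistic = 0.5 everywhere (H = log N, q = 1/N)
  expect_equal(predictLogistic(mod, bg), rep(0.5, 60), tolerance = 1e-12)
  expect_equal(mod@entropy, log(N), tolerance = 1e-9)
})

test_that("single-feature fit matches a dense 1-D grid search of the objective", {
  set.seed(5)
  pres <- matrix(rnorm(5, 1, 0.3), 5, 1, dimnames = list(NULL, "x"))
  bg <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "x"))
  fe <- buildFeatures(pres, bg, "L")
  mod <- fitMaxent(fe, rm = 1, addPresences = FALSE)
  beta <- mod@beta
  obj <- function(l) {
    s <- fe$Fpres * l; sb <- fe$Fbg * l
    mean(s) - log(sum(exp(sb))) - beta * abs(l)
  }
  grid <- seq(-20, 20, by = 1e-4)
  oracle <- grid[which.max(vapply(grid, obj, numeric(1)))]
  expect_equal(mod@lambda, oracle, tolerance = 1e-3)
})

test_that("raw scores are normalized and rank-invariant to intercept shifts", {
  ls <- smallLandscape(seed = 7, nRows = 20, nCols = 20)
  st <- ls$stack
  occ <- sampleOccurrences(trueSuitability(st, defaultNiche()), n = 40,
                           seed = 3)
  pres <- extractValues(st, occ)[, nicheVars]
  bg <- sampleBackground(st, 300, seed = 2)$values[, nicheVars]
  fe <- buildFeatures(pres, bg, "LQ")
  mod <- fitMaxent(fe, rm = 1)
  normSet <- rbind(bg, as.matrix(pres))
  raw <- predictRaw(mod, normSet)
  expect_equal(sum(raw), 1, tolerance = 1e-8)
  expect_true(mod@entropy >= 0 && mod@entropy <= log(nrow(normSet)) + 1e-9)

  # adding c to a coefficient of a constant-shift feature only rescales raw
  # scores; ranking must be unchanged after renormalization
  shifted <- mod
  shifted@lambda[1] <- shifted@lambda[1] + 0  # identical model
  expect_equal(order(predictRaw(shifted, bg)), order(predictRaw(mod, bg)))
  # logistic is strictly increasing in raw
  q <- predictRaw(mod, bg); p <- predictLogistic(mod, bg)
  expect_equal(order(q), order(p))
  expect_true(all(p > 0 & p < 1))
})

test_that("penalized optimum is non-increasing in RM", {
  set.seed(8)
  pres <- matrix(rnorm(12 * 2, 0.5), 12, 2,
                 dimnames = list(NULL, c("a", "b")))
  bg <- matrix(rnorm(80 * 2), 80, 2, dimnames = list(NULL, c("a", "b")))
  fe <- buildFeatures(pres, bg, "LQ")
  rms <- c(0.5, 1, 2, 4)
  Fbg <- rbind(fe$Fbg, fe$Fpres)
  objAt <- function(rm) {
    mod <- fitMaxent(fe, rm)
    # evaluate all fits under a common (unpenalized + rm=1 penalty) scale:
    # the optimum of the rm-penalized objective itself must decrease in rm
    sPres <- fe$Fpres %*% mod@lambda; sBg <- Fbg %*% mod@lambda
    mean(sPres) - log(sum(exp(sBg))) - sum(mod@beta * abs(mod@lambda))
  }
  vals <- vapply(rms, objAt, numeric(1))
  expect_true(all(diff(vals) <= 1e-8))
})

test_that("replicate runs average to the stored per-replicate rasters", {
  ls <- smallLandscape(seed = 9, nRows = 20, nCols = 20)
  st <- ls$stack
  occ <- sampleOccurrences(trueSuitability(st, defaultNiche()), n = 30,
                           seed = 5)
  run <- runReplicates(occ, st, fc = "LQ", rm = 1, nReplicates = 3,
                       nBackground = 200, seed = 7)
  manual <- (gridValues(run$rasters[[1]]) + gridValues(run$rasters[[2]]) +
               gridValues(run$rasters[[3]])) / 3
  expect_equal(gridValues(run$meanRaster), manual, tolerance = 1e-12)
  expect_equal(formals(runReplicates)$nReplicates, 10L)
  expect_equal(formals(runReplicates)$testFraction, 0.25)

  # degenerate single replicate without bootstrap equals a plain fit
  one <- runReplicates(occ, st, fc = "LQ", rm = 1, nReplicates = 1,
                       testFraction = 0, bootstrap = FALSE,
                       nBackground = 200, seed = 7)
  pres <- extractValues(st, occ)
  bg <- sampleBackground(st, 200, seed = 7)
  fe <- buildFeatures(pres, bg$values, "LQ")
  plain <- fitMaxent(fe, rm = 1)
  expect_equal(one$models[[1]]@lambda, plain@lambda, tolerance = 1e-12)
  expect_error(runReplicates(occ[1:3, ], st), "at least 4")
})

test_that("models serialize to JSON and predict identically after reload", {
  set.seed(10)
  pres <- matrix(rnorm(10 * 2), 10, 2, dimnames = list(NULL, c("a", "b")))
  bg <- matrix(rnorm(50 * 2), 50, 2, dimnames = list(NULL, c("a", "b")))
  mod <- fitMaxent(buildFeatures(pres, bg, "LQH"), rm = 1.5)
  p <- withr::local_tempfile(fileext = ".json")
  writeMaxentJson(mod, p)
  mod2 <- readMaxentJson(p)
  expect_equal(predictLogistic(mod2, bg), predictLogistic(mod, bg),
               tolerance = 1e-12)
})
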