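# Presence-background maximum-entropy model: background sampling, L1
# penalized fitting by cyclic coordinate descent, raw and logistic
# prediction, and bootstrap replicate runs.

#' Fitted maximum-entropy habitat model
#'
#' The Gibbs distribution over background cells
#' \eqn{q(x) = e^{\lambda f(x)}/Z} maximizing the penalized log likelihood
#' of the presences. Slots hold the feature expansion, coefficients, the
#' per-feature L1 penalties, the background log-normalizer and the entropy
#' of the fitted background distribution (used by the logistic transform).
#'
#' @slot features the \code{featureExpansion} (defs, scaling, design).
#' @slot lambda numeric coefficient vector, one per feature.
#' @slot beta numeric per-feature penalties (already scaled by RM).
#' @slot logZ log normalizer over the background.
#' @slot entropy entropy H of the fitted background distribution.
#' @slot rm regularization multiplier.
#' @slot fc feature-combination label.
#' @slot converged logical convergence flag.
#' @slot trace data.frame of per-update objective increments (for percent
#'   contribution).
#' @slot meta list of training metadata (seed, replicate id, counts).
#'
#' @export
setClass("MaxentModel",
  representation(features = "list", lambda = "numeric", beta = "numeric",
                 logZ = "numeric", entropy = "numeric", rm = "numeric",
                 fc = "character", converged = "logical", trace = "list",
                 meta = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@lambda) != nrow(object@features$defs))
      msg <- c(msg, "lambda length must match the feature count")
    if (length(object@beta) != length(object@lambda))
      msg <- c(msg, "beta length must match lambda")
    if (object@entropy < -1e-9) msg <- c(msg, "entropy must be >= 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "MaxentModel", function(object) {
  nz <- sum(abs(object@lambda) > 1e-8)
  cat(sprintf("MaxentModel: FC = %s, RM = %g, %d/%d nonzero coefficients\n",
              object@fc, object@rm, nz, length(object@lambda)))
  cat(sprintf("  presences: %d, background: %d, entropy H = %.4f, %s\n",
              object@meta$nPresence, object@meta$nBackground,
              object@entropy,
              if (object@converged) "converged" else "NOT converged"))
})

#' @rdname MaxentModel-class
#' @param model a \code{MaxentModel}
#' @export
coefMaxent <- function(model) setNames(model@lambda,
                                       model@features$defs$name)

#' @rdname MaxentModel-class
#' @export
modelEntropy <- function(model) model@entropy

#' Sample background cells uniformly from the land mask
#'
#' @param stack a \linkS4class{PredictorStack}.
#' @param n maximum number of background points (default 10000).
#' @param seed integer RNG seed.
#' @return List of class \code{"backgroundSample"}: \code{cells} (linear
#'   indices), \code{values} (cell-by-layer matrix), \code{seed}.
#' @export
sampleBackground <- function(stack, n = 10000L, seed = 1L) {
  land <- which(landMask(stack))
  if (length(land) == 0) stop("stack has no land cells")
  set.seed(seed)
  cells <- if (length(land) <= n) land else
    land[sample.int(length(land), n, replace = FALSE)]
  structure(list(cells = cells, values = stackValues(stack, cells),
                 seed = seed), class = "backgroundSample")
}

# Published default per-class base penalties, linearly interpolated on the
# presence count m (flat beyond the table ends).
basePenalty <- function(class, m) {
  interp <- function(xs, ys) {
    if (m <= xs[1]) return(ys[1])
    if (m >= xs[length(xs)]) return(ys[length(ys)])
    stats::approx(xs, ys, xout = m)$y
  }
  switch(class,
         L = , Q = , P = interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
         H = 0.5,
         T = interp(c(0, 100), c(2, 1)))
}

# Per-feature penalties: rm * class base(m) * sd over presences (floored)
# / sqrt(m) — the reference schedule for [0,1]-scaled features.
featurePenalties <- function(fe, rm) {
  m <- nrow(fe$Fpres)
  s <- pmax(apply(fe$Fpres, 2, sd), 0.05)
  base <- vapply(fe$defs$class, basePenalty, numeric(1), m = m)
  rm * base * s / sqrt(m)
}

# Penalized objective: mean presence score - logZ - sum(beta |lambda|).
maxentObjective <- function(lambda, Fpres, Fbg, beta) {
  sPres <- as.vector(Fpres %*% lambda)
  sBg <- as.vector(Fbg %*% lambda)
  mx <- max(sBg)
  logZ <- mx + log(sum(exp(sBg - mx)))
  mean(sPres) - logZ - sum(beta * abs(lambda))
}

#' Fit a maximum-entropy model
#'
#' Maximizes \eqn{\frac1m\sum_i \lambda f(x_i) - \log\sum_b e^{\lambda f(b)}
#' - \sum_j \beta_j|\lambda_j|} by cyclic coordinate descent with
#' closed-form soft-threshold updates on a local quadratic bound.
#' Penalties follow the published per-class default schedule (interpolated
#' on presence count, scaled by presence-sd and \eqn{1/\sqrt m}) times the
#' regularization multiplier. By default presences are appended to the
#' background for normalization (target-group union).
#'
#' @param fe a \code{\link{buildFeatures}} expansion.
#' @param rm regularization multiplier (> 0).
#' @param addPresences append presences to the normalization background.
#' @param maxCycles,tol convergence controls: stop when a full cycle
#'   improves the objective by less than \code{tol} (default 1e-6) or after
#'   \code{maxCycles} (default 500) cycles.
#' @param meta list merged into the model's training metadata.
#' @return A \linkS4class{MaxentModel}. Non-convergence returns the best
#'   iterate with \code{converged = FALSE} and a warning.
#' @export
fitMaxent <- function(fe, rm = 1, addPresences = TRUE, maxCycles = 500L,
                      tol = 1e-6, meta = list()) {
  stopifnot(inherits(fe, "featureExpansion"))
  m <- nrow(fe$Fpres)
  if (m < 2) stop("need at least 2 presences")
  if (nrow(fe$Fbg) < 1) stop("background is empty")
  Fbg <- if (addPresences) rbind(fe$Fbg, fe$Fpres) else fe$Fbg
  Fpres <- fe$Fpres
  N <- nrow(Fbg); J <- ncol(Fbg)
  beta <- featurePenalties(fe, rm)
  pbar <- colMeans(Fpres)

  lambda <- numeric(J)
  sBg <- numeric(N)           # lambda . f over background
  obj <- maxentObjective(lambda, Fpres, Fbg, beta)
  traceFeat <- integer(0); traceDelta <- numeric(0)
  converged <- FALSE
  for (cycle in seq_len(maxCycles)) {
    objStart <- obj
    mx <- max(sBg)
    w <- exp(sBg - mx); Zs <- sum(w)
    for (j in seq_len(J)) {
      fj <- Fbg[, j]
      Ej <- sum(w * fj) / Zs
      Vj <- sum(w * fj * fj) / Zs - Ej^2
      h <- max(Vj, 1e-6)
      g <- pbar[j] - Ej
      z <- lambda[j] + g / h
      newl <- sign(z) * max(abs(z) - beta[j] / h, 0)
      if (newl != lambda[j]) {
        dl <- newl - lambda[j]
        # objective change from this single-coordinate move
        newW <- w * exp(dl * fj)
        newZs <- sum(newW)
        dObj <- pbar[j] * dl - log(newZs / Zs) -
          beta[j] * (abs(newl) - abs(lambda[j]))
        if (dObj < 0) { next }  # bound failed; skip (rare)
        lambda[j] <- newl
        sBg <- sBg + dl * fj
        w <- newW; Zs <- newZs
        obj <- obj + dObj
        traceFeat <- c(traceFeat, j); traceDelta <- c(traceDelta, dObj)
      }
    }
    if (obj - objStart < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("coordinate descent did not converge in ", maxCycles, " cycles")

  mx <- max(sBg)
  logZ <- mx + log(sum(exp(sBg - mx)))
  q <- exp(sBg - logZ)
  H <- -sum(q * log(pmax(q, 1e-300)))
  new("MaxentModel",
      features = unclass(fe)[c("defs", "scaling", "fc", "varNames",
                               "nKnots")],
      lambda = lambda, beta = beta, logZ = logZ, entropy = H, rm = rm,
      fc = fe$fc, converged = converged,
      trace = list(feature = traceFeat, delta = traceDelta),
      meta = c(meta, list(nPresence = m, nBackground = nrow(fe$Fbg),
                          nNorm = N, addPresences = addPresences)))
}

# Rebuild a featureExpansion view of the stored definitions for prediction.
modelExpansion <- function(model) {
  structure(model@features, class = "featureExpansion")
}

#' Raw (Gibbs) prediction
#'
#' \eqn{q(x) = e^{\lambda f(x)}/Z} with Z the stored background normalizer;
#' raw scores over the fitting background sum to 1.
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param values matrix/data.frame of predictor values with the model's
#'   variables as columns.
#' @return Numeric vector of raw scores.
#' @export
predictRaw <- function(model, values) {
  Fm <- featureMatrix(modelExpansion(model), values)
  as.vector(exp(Fm %*% model@lambda - model@logZ))
}

#' Logistic prediction
#'
#' The standard logistic output \eqn{p = e^H q/(1 + e^H q)} with H the
#' entropy of the fitted background distribution; values lie in (0, 1) and
#' a null model scores 0.5 everywhere.
#'
#' @inheritParams predictRaw
#' @return Numeric vector of suitabilities in (0, 1).
#' @export
predictLogistic <- function(model, values) {
  q <- predictRaw(model, values)
  eh <- exp(model@entropy)
  eh * q / (1 + eh * q)
}

#' Predict a logistic suitability raster over a stack
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param stack a \linkS4class{PredictorStack} carrying all model variables.
#' @return A \linkS4class{RasterGrid} of logistic suitability.
#' @export
predictSuitability <- function(model, stack) {
  out <- stackTemplate(stack)
  cells <- which(landMask(stack))
  vals <- stackValues(stack, cells)
  out@values[cells] <- predictLogistic(model, vals)
  out
}

#' Bootstrap replicate runs and mean suitability surface
#'
#' Replicated fitting in the usual presence-background protocol: per
#' replicate a fraction of presences is held out for testing, the training
#' presences are drawn by bootstrap from the remainder, a model is fitted,
#' and the mean logistic raster across replicates is returned as the
#' working suitability surface.
#'
#' @param occ occurrence data.frame (cleaned/thinned).
#' @param stack a \linkS4class{PredictorStack}.
#' @param fc feature combination (default the tuned \code{"LQH"}).
#' @param rm regularization multiplier (default the tuned 1.5).
#' @param nReplicates number of replicates (default 10).
#' @param testFraction held-out presence fraction (default 0.25).
#' @param nBackground background size (default 10000).
#' @param bootstrap draw training presences with replacement (default TRUE);
#'   with \code{nReplicates = 1}, \code{testFraction = 0} and
#'   \code{bootstrap = FALSE} this reduces to a single plain fit.
#' @param seed integer RNG seed.
#' @param ... passed to \code{\link{fitMaxent}}.
#' @return List of class \code{"replicateRun"}: \code{models},
#'   \code{evals} (data.frame trainAUC/testAUC per replicate),
#'   \code{meanRaster}, \code{rasters}, \code{background}.
#' @export
runReplicates <- function(occ, stack, fc = "LQH", rm = 1.5,
                          nReplicates = 10L, testFraction = 0.25,
                          nBackground = 10000L, bootstrap = TRUE,
                          seed = 1L, ...) {
  presAll <- extractValues(stack, occ)
  m <- nrow(presAll)
  if (m < 4) stop("need at least 4 presences for replicate runs")
  bg <- sampleBackground(stack, nBackground, seed = seed)
  models <- vector("list", nReplicates)
  rasters <- vector("list", nReplicates)
  evals <- data.frame(trainAUC = numeric(nReplicates),
                      testAUC = numeric(nReplicates))
  for (r in seq_len(nReplicates)) {
    set.seed(seed + r)
    nTest <- floor(m * testFraction)
    testIdx <- if (nTest > 0) sample.int(m, nTest) else integer(0)
    trainPool <- setdiff(seq_len(m), testIdx)
    trainIdx <- if (bootstrap)
      sample(trainPool, length(trainPool), replace = TRUE) else trainPool
    fe <- buildFeatures(presAll[trainIdx, , drop = FALSE], bg$values, fc)
    mod <- fitMaxent(fe, rm, meta = list(seed = seed, replicate = r), ...)
    models[[r]] <- mod
    rasters[[r]] <- predictSuitability(mod, stack)
    bgScore <- predictLogistic(mod, bg$values)
    evals$trainAUC[r] <- auc(predictLogistic(
      mod, presAll[trainIdx, , drop = FALSE]), bgScore)
    evals$testAUC[r] <- if (nTest > 0) auc(predictLogistic(
      mod, presAll[testIdx, , drop = FALSE]), bgScore) else NA_real_
  }
  meanVals <- Reduce(`+`, lapply(rasters, gridValues)) / nReplicates
  meanRaster <- rasterGrid(meanVals, stack@xll, stack@yll, stack@cellSize)
  structure(list(models = models, evals = evals, meanRaster = meanRaster,
                 rasters = rasters, background = bg),
            class = "replicateRun")
}

#' Serialize / restore a model as JSON
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param path JSON file path.
#' @return \code{readMaxentJson} returns a \linkS4class{MaxentModel}
#'   (without the training trace).
#' @export
writeMaxentJson <- function(model, path) {
  sc <- model@features$scaling
  jsonlite::write_json(list(
    fc = model@fc, rm = model@rm,
    defs = model@features$defs,
    scaling = list(lo = as.list(sc$lo), hi = as.list(sc$hi),
                   prodRange = sc$prodRange),
    varNames = model@features$varNames, nKnots = model@features$nKnots,
    lambda = model@lambda, beta = model@beta, logZ = model@logZ,
    entropy = model@entropy, converged = model@converged,
    meta = model@meta), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMaxentJson
#' @export
readMaxentJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- list(lo = unlist(x$scaling$lo), hi = unlist(x$scaling$hi),
             prodRange = lapply(x$scaling$prodRange, unlist))
  new("MaxentModel",
      features = list(defs = as.data.frame(x$defs), scaling = sc,
                      fc = x$fc, varNames = x$varNames, nKnots = x$nKnots),
      lambda = x$lambda, beta = x$beta, logZ = x$logZ, entropy = x$entropy,
      rm = x$rm, fc = x$fc, converged = x$converged,
      trace = list(feature = integer(0), delta = numeric(0)),
      meta = as.list(x$meta))
}
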