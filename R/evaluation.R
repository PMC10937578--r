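# Model accuracy metrics, variable importance and response curves.

#' Rank-based AUC for presence vs background scores
#'
#' The Mann-Whitney probability that a random presence outranks a random
#' background point, ties counted one half.
#'
#' @param presScores,bgScores numeric score vectors (non-empty).
#' @return AUC in [0, 1].
#' @export
auc <- function(presScores, bgScores) {
  if (!length(presScores) || !length(bgScores))
    stop("score vectors must be non-empty")
  np <- length(presScores); nb <- length(bgScores)
  r <- rank(c(presScores, bgScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

# Sensitivity/specificity over all candidate thresholds (the distinct
# observed scores); predicted presence means score >= threshold.
thresholdScan <- function(presScores, bgScores) {
  th <- sort(unique(c(presScores, bgScores)))
  sens <- vapply(th, function(t) mean(presScores >= t), numeric(1))
  spec <- vapply(th, function(t) mean(bgScores < t), numeric(1))
  list(threshold = th, sens = sens, spec = spec)
}

#' Maximum true skill statistic
#'
#' Maximizes sensitivity + specificity - 1 over the distinct observed
#' scores (exact optimum); the smallest maximizing threshold is returned.
#'
#' @inheritParams auc
#' @return List with \code{tss} and \code{threshold}.
#' @export
maxTSS <- function(presScores, bgScores) {
  sc <- thresholdScan(presScores, bgScores)
  tss <- sc$sens + sc$spec - 1
  i <- which.max(tss)
  list(tss = tss[i], threshold = sc$threshold[i])
}

#' Maximum Cohen's kappa
#'
#' Kappa of the 2x2 confusion table (presences vs background as
#' pseudo-absences), maximized over the distinct observed scores.
#'
#' @inheritParams auc
#' @return List with \code{kappa} and \code{threshold}.
#' @export
maxKappa <- function(presScores, bgScores) {
  np <- length(presScores); nb <- length(bgScores); n <- np + nb
  sc <- thresholdScan(presScores, bgScores)
  kap <- vapply(seq_along(sc$threshold), function(i) {
    tp <- sc$sens[i] * np; fn <- np - tp
    tn <- sc$spec[i] * nb; fp <- nb - tn
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    if (abs(1 - pe) < 1e-12) 0 else (po - pe) / (1 - pe)
  }, numeric(1))
  i <- which.max(kap)
  list(kappa = kap[i], threshold = sc$threshold[i])
}

#' Percent contribution from the training trace
#'
#' Credits each coordinate-descent update's objective gain to the
#' environmental variable behind the updated feature (product features
#' split equally between their two variables), floors negative totals at
#' zero, and normalizes to sum 100.
#'
#' @param model a \linkS4class{MaxentModel} with a training trace.
#' @return Named numeric vector summing to 100.
#' @export
percentContribution <- function(model) {
  tr <- model@trace
  if (!length(tr$feature)) stop("model has no training trace")
  d <- model@features$defs
  vars <- model@features$varNames
  acc <- setNames(numeric(length(vars)), vars)
  for (i in seq_along(tr$feature)) {
    f <- tr$feature[i]
    if (d$class[f] == "P") {
      acc[d$var1[f]] <- acc[d$var1[f]] + tr$delta[i] / 2
      acc[d$var2[f]] <- acc[d$var2[f]] + tr$delta[i] / 2
    } else acc[d$var1[f]] <- acc[d$var1[f]] + tr$delta[i]
  }
  acc <- pmax(acc, 0)
  if (sum(acc) == 0) return(setNames(rep(100 / length(acc), length(acc)),
                                     vars))
  100 * acc / sum(acc)
}

#' Permutation importance
#'
#' For each variable, its values are permuted across the combined
#' presence-plus-background table, training AUC is recomputed, and the
#' importance is the AUC drop (floored at zero), normalized to sum 100.
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param presValues,bgValues predictor value tables used in training.
#' @param seed RNG seed for the permutations.
#' @param nRepeats permutations per variable (default 1, averaged if more).
#' @return Named numeric vector summing to 100.
#' @export
permutationImportance <- function(model, presValues, bgValues, seed = 1L,
                                  nRepeats = 1L) {
  presValues <- as.matrix(presValues); bgValues <- as.matrix(bgValues)
  np <- nrow(presValues)
  all <- rbind(presValues, bgValues)
  base <- auc(predictRaw(model, presValues), predictRaw(model, bgValues))
  set.seed(seed)
  drops <- vapply(model@features$varNames, function(v) {
    mean(vapply(seq_len(nRepeats), function(r) {
      perm <- all
      perm[, v] <- perm[sample.int(nrow(perm)), v]
      a <- auc(predictRaw(model, perm[seq_len(np), , drop = FALSE]),
               predictRaw(model, perm[-seq_len(np), , drop = FALSE]))
      max(0, base - a)
    }, numeric(1)))
  }, numeric(1))
  if (sum(drops) == 0) {
    warning("no permutation changes the AUC; importance set uniform")
    return(setNames(rep(100 / length(drops), length(drops)),
                    model@features$varNames))
  }
  100 * drops / sum(drops)
}

# Regularized training gain: mean presence log-raw + log N over the
# normalization background, minus the L1 penalty. Zero for a null model.
regularizedGain <- function(model, presValues, penalized = TRUE) {
  q <- predictRaw(model, presValues)
  g <- mean(log(pmax(q, 1e-300))) + log(model@meta$nNorm)
  if (penalized) g <- g - sum(model@beta * abs(model@lambda))
  g
}

#' Jackknife variable-importance table
#'
#' Fits, for each variable, a model with only that variable and a model
#' without it (single train/test split, no bootstrap), and records
#' regularized training gain, test gain and test AUC alongside the
#' full-model row.
#'
#' @param occ occurrence data.frame.
#' @param stack a \linkS4class{PredictorStack}.
#' @param fc,rm model settings.
#' @param testFraction held-out fraction (default 0.25).
#' @param nBackground background size.
#' @param seed RNG seed for split and background.
#' @return data.frame with columns variable, mode
#'   (\code{only}/\code{without}/\code{full}), trainGain, testGain, testAUC.
#' @export
jackknife <- function(occ, stack, fc = "LQH", rm = 1.5,
                      testFraction = 0.25, nBackground = 10000L,
                      seed = 1L) {
  vars <- layerNames(stack)
  if (length(vars) < 2) stop("need at least 2 variables")
  presAll <- extractValues(stack, occ)
  bg <- sampleBackground(stack, nBackground, seed = seed)
  m <- nrow(presAll)
  set.seed(seed)
  testIdx <- sample.int(m, max(1L, floor(m * testFraction)))
  trainIdx <- setdiff(seq_len(m), testIdx)

  fitSubset <- function(cols) {
    fe <- buildFeatures(presAll[trainIdx, cols, drop = FALSE],
                        bg$values[, cols, drop = FALSE], fc)
    mod <- fitMaxent(fe, rm)
    data.frame(
      trainGain = regularizedGain(mod, presAll[trainIdx, cols,
                                               drop = FALSE]),
      testGain = regularizedGain(mod, presAll[testIdx, cols,
                                              drop = FALSE],
                                 penalized = FALSE),
      testAUC = auc(predictRaw(mod, presAll[testIdx, cols, drop = FALSE]),
                    predictRaw(mod, bg$values[, cols, drop = FALSE])))
  }
  rows <- list()
  for (v in vars) {
    rows[[paste0(v, ".only")]] <- cbind(variable = v, mode = "only",
                                        fitSubset(v))
    rows[[paste0(v, ".without")]] <- cbind(variable = v, mode = "without",
                                           fitSubset(setdiff(vars, v)))
  }
  rows[["full"]] <- cbind(variable = "(all)", mode = "full",
                          fitSubset(vars))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Response curve of one variable
#'
#' Sweeps the variable over its observed (training) range with every other
#' variable fixed at its background mean, and reports the logistic output
#' plus the band(s) where the output exceeds 0.5 (the optimally suitable
#' band).
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param variable variable name.
#' @param bgValues background value table supplying the fixed means.
#' @param nGrid sweep resolution (default 100).
#' @return List of class \code{"responseCurve"}: \code{variable},
#'   \code{grid}, \code{response}, \code{band} (data.frame lower/upper, one
#'   row per contiguous >0.5 interval).
#' @export
responseCurve <- function(model, variable, bgValues, nGrid = 100L) {
  vars <- model@features$varNames
  if (!variable %in% vars) stop("unknown variable '", variable, "'")
  bgValues <- as.matrix(bgValues)
  lo <- model@features$scaling$lo[variable]
  hi <- model@features$scaling$hi[variable]
  grid <- seq(lo, hi, length.out = nGrid)
  sweep <- matrix(rep(colMeans(bgValues[, vars, drop = FALSE]),
                      each = nGrid), nGrid, length(vars),
                  dimnames = list(NULL, vars))
  sweep[, variable] <- grid
  p <- predictLogistic(model, sweep)
  above <- p > 0.5
  band <- if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    data.frame(lower = grid[starts[r$values]],
               upper = grid[ends[r$values]])
  } else data.frame(lower = numeric(), upper = numeric())
  structure(list(variable = variable, grid = grid, response = p,
                 band = band), class = "responseCurve")
}

#' Full evaluation report for a replicate run
#'
#' @param run a \code{\link{runReplicates}} result.
#' @param occ the occurrences used for the run.
#' @param stack the predictor stack.
#' @return List of class \code{"evalReport"}: train/test AUC mean and sd,
#'   max TSS and kappa (best-replicate model scored on all presences vs the
#'   background), percent contribution and permutation importance.
#' @export
evalReport <- function(run, occ, stack) {
  presValues <- extractValues(stack, occ)
  bgValues <- run$background$values
  best <- run$models[[which.max(run$evals$testAUC)]]
  ps <- predictLogistic(best, presValues)
  bs <- predictLogistic(best, bgValues)
  tss <- maxTSS(ps, bs); kap <- maxKappa(ps, bs)
  structure(list(
    trainAUC = mean(run$evals$trainAUC), trainAUCsd = sd(run$evals$trainAUC),
    testAUC = mean(run$evals$testAUC), testAUCsd = sd(run$evals$testAUC),
    tss = tss$tss, tssThreshold = tss$threshold,
    kappa = kap$kappa, kappaThreshold = kap$threshold,
    percentContribution = percentContribution(best),
    permutationImportance = permutationImportance(best, presValues,
                                                  bgValues)),
    class = "evalReport")
}

#' @export
print.evalReport <- function(x, ...) {
  cat(sprintf("evalReport: train AUC %.3f +/- %.3f, test AUC %.3f +/- %.3f\n",
              x$trainAUC, x$trainAUCsd, x$testAUC, x$testAUCsd))
  cat(sprintf("  max TSS %.3f (thr %.3f), max kappa %.3f (thr %.3f)\n",
              x$tss, x$tssThreshold, x$kappa, x$kappaThreshold))
  pc <- sort(x$percentContribution, decreasing = TRUE)
  cat("  top contributions:",
      paste(sprintf("%s %.1f%%", names(pc)[seq_len(min(4, length(pc)))],
                    pc[seq_len(min(4, length(pc)))]), collapse = ", "),
      "\n")
  invisible(x)
}
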