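# Regularization-multiplier x feature-combination grid search with
# small-sample AICc selection.

#' Candidate RM x FC tuning grid
#'
#' Full cross product in deterministic order (feature combination outer,
#' regularization multiplier inner). The defaults — RM 0.5 to 4 in steps of
#' 0.5 crossed with L, LQ, H, LQH, LQHP, LQHPT — give 48 candidates.
#'
#' @param rm numeric vector of regularization multipliers.
#' @param fc character vector of feature combinations.
#' @return data.frame with columns \code{fc}, \code{rm}.
#' @export
candidateGrid <- function(rm = seq(0.5, 4, by = 0.5),
                          fc = c("L", "LQ", "H", "LQH", "LQHP", "LQHPT")) {
  if (!length(rm) || !length(fc)) stop("rm and fc must be non-empty")
  data.frame(fc = rep(fc, each = length(rm)),
             rm = rep(rm, times = length(fc)),
             stringsAsFactors = FALSE)
}

#' Small-sample AICc of a fitted model
#'
#' Raw scores are standardized to sum 1 over all land cells; the log
#' likelihood is the sum of log standardized scores at the presences;
#' k counts coefficients with \code{|lambda| > 1e-8};
#' \eqn{AICc = 2k - 2\ln L + 2k(k+1)/(n-k-1)}. The value is flagged
#' invalid when \eqn{k \ge n-1}.
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param presValues predictor values at the n presences (n >= 2).
#' @param landValues predictor values of all land cells.
#' @return List: \code{aicc}, \code{k}, \code{lnL}, \code{valid}.
#' @export
aicc <- function(model, presValues, landValues) {
  n <- nrow(as.matrix(presValues))
  if (n < 2) stop("need at least 2 presences")
  rawLand <- predictRaw(model, landValues)
  rawPres <- predictRaw(model, presValues)
  s <- sum(rawLand)
  lnL <- sum(log(pmax(rawPres / s, 1e-300)))
  k <- sum(abs(model@lambda) > 1e-8)
  if (k >= n - 1)
    return(list(aicc = NA_real_, k = k, lnL = lnL, valid = FALSE))
  list(aicc = 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1), k = k,
       lnL = lnL, valid = TRUE)
}

#' Mean train-minus-test AUC difference over replicates
#'
#' @param evals data.frame with columns \code{trainAUC}, \code{testAUC}.
#' @return Arithmetic mean of the per-replicate differences.
#' @export
avgDiffAuc <- function(evals) {
  if (!nrow(evals)) stop("need at least one replicate")
  mean(evals$trainAUC - evals$testAUC)
}

#' Evaluate the tuning grid and select a model
#'
#' For every candidate, a model is fitted on the full presence set (no
#' split) for AICc, and the replicate scheme supplies avg.diff.AUC.
#' delta.AICc is AICc minus the grid minimum; the candidate with
#' delta.AICc = 0 is selected, ties broken by smaller RM then fewer
#' feature classes.
#'
#' @param occ occurrence data.frame.
#' @param stack a \linkS4class{PredictorStack}.
#' @param grid candidate data.frame from \code{\link{candidateGrid}}.
#' @param nBackground background size.
#' @param nReplicates replicates per candidate for avg.diff.AUC (0 skips
#'   the replicate stage and reports NA).
#' @param testFraction held-out fraction for the replicate stage.
#' @param seed RNG seed.
#' @return List of class \code{"tuningResult"}: \code{table} (fc, rm, k,
#'   AICc, delta.AICc, avg.diff.AUC, valid) and \code{selected} (row of the
#'   winning candidate).
#' @export
evaluateGrid <- function(occ, stack, grid = candidateGrid(),
                         nBackground = 10000L, nReplicates = 10L,
                         testFraction = 0.25, seed = 1L) {
  presValues <- extractValues(stack, occ)
  bg <- sampleBackground(stack, nBackground, seed = seed)
  landValues <- stackValues(stack)
  tab <- grid
  tab$k <- NA_integer_; tab$AICc <- NA_real_
  tab$avg.diff.AUC <- NA_real_; tab$valid <- FALSE
  for (i in seq_len(nrow(grid))) {
    fe <- buildFeatures(presValues, bg$values, grid$fc[i])
    mod <- fitMaxent(fe, grid$rm[i])
    ic <- aicc(mod, presValues, landValues)
    tab$k[i] <- ic$k; tab$AICc[i] <- ic$aicc; tab$valid[i] <- ic$valid
    if (nReplicates > 0) {
      rep <- runReplicates(occ, stack, grid$fc[i], grid$rm[i],
                           nReplicates = nReplicates,
                           testFraction = testFraction,
                           nBackground = nBackground, seed = seed)
      tab$avg.diff.AUC[i] <- avgDiffAuc(rep$evals)
    }
  }
  if (!any(tab$valid)) stop("no candidate produced a valid AICc")
  best <- min(tab$AICc[tab$valid])
  tab$delta.AICc <- tab$AICc - best
  cand <- which(tab$valid & tab$delta.AICc <= 1e-9)
  cand <- cand[order(tab$rm[cand], nchar(tab$fc[cand]))]
  sel <- cand[1]
  structure(list(table = tab, selected = tab[sel, , drop = FALSE]),
            class = "tuningResult")
}

#' @export
print.tuningResult <- function(x, ...) {
  cat(sprintf("tuningResult: %d candidates, selected FC = %s, RM = %g\n",
              nrow(x$table), x$selected$fc, x$selected$rm))
  print(head(x$table[order(x$table$delta.AICc), ], 6))
  invisible(x)
}

#' Write a tuning table as CSV
#'
#' @param result a \code{tuningResult}.
#' @param path CSV path.
#' @export
writeTuningTable <- function(result, path) {
  write.csv(result$table[, c("fc", "rm", "k", "AICc", "delta.AICc",
                             "avg.diff.AUC", "valid")],
            path, row.names = FALSE)
  invisible(path)
}
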