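# Predictor collinearity screening: pairwise Pearson cull followed by
# iterative VIF elimination.

#' Screen predictors for collinearity
#'
#' Two-stage screen. Stage 1: among every pair with \code{|r| >=
#' rThreshold}, the lower-priority member is dropped (pairs processed in
#' decreasing \code{|r|}); priority is the position in \code{priority}
#' (unlisted variables rank below all listed ones, ties broken by input
#' column order). Stage 2: variance inflation factors
#' \eqn{VIF_j = 1/(1-R^2_j)} from regressing each variable on the others
#' are computed and the highest-VIF variable is dropped until all are below
#' \code{vifThreshold}. A perfectly collinear remainder is reduced down to a
#' single variable if necessary.
#'
#' @param values data.frame or matrix of predictor values (samples x
#'   variables), typically from \code{\link{extractValues}} at occurrences
#'   plus a background sample.
#' @param rThreshold pairwise Pearson cut, default 0.7.
#' @param vifThreshold VIF cut, default 5.
#' @param priority character vector, most-preferred first; stands in for
#'   expert judgement about which variables to keep.
#' @return A list of class \code{"screenReport"}: \code{cor} (full Pearson
#'   matrix), \code{vif} (VIFs of the retained set), \code{retained},
#'   \code{dropped} (data.frame of name, stage, reason).
#' @export
screenPredictors <- function(values, rThreshold = 0.7, vifThreshold = 5,
                             priority = character()) {
  values <- as.data.frame(values)
  if (ncol(values) < 2) stop("need at least 2 variables")
  if (nrow(values) < 3) stop("need at least 3 samples")
  nm <- colnames(values)
  rank <- match(nm, priority)
  rank[is.na(rank)] <- length(priority) + seq_len(sum(is.na(rank)))
  C <- cor(as.matrix(values))

  retained <- nm
  dropped <- data.frame(name = character(), stage = character(),
                        reason = character(), stringsAsFactors = FALSE)
  pairs <- which(upper.tri(C) & abs(C) >= rThreshold, arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(-abs(C[pairs]))
    for (p in ord) {
      a <- nm[pairs[p, 1]]; b <- nm[pairs[p, 2]]
      if (!(a %in% retained) || !(b %in% retained)) next
      loser <- if (rank[match(a, nm)] <= rank[match(b, nm)]) b else a
      winner <- setdiff(c(a, b), loser)
      retained <- setdiff(retained, loser)
      dropped <- rbind(dropped, data.frame(
        name = loser, stage = "correlation",
        reason = sprintf("|r| = %.3f with %s", abs(C[pairs[p, 1],
                                                     pairs[p, 2]]), winner),
        stringsAsFactors = FALSE))
    }
  }

  vifOf <- function(vars) {
    vapply(vars, function(v) {
      fit <- lm(stats::reformulate(sprintf("`%s`", setdiff(vars, v)),
                                   response = sprintf("`%s`", v)),
                data = values)
      r2 <- summary(fit)$r.squared
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  vif <- if (length(retained) >= 2) vifOf(retained) else
    setNames(rep(1, length(retained)), retained)
  while (length(retained) >= 2 && max(vif) >= vifThreshold) {
    worst <- retained[which.max(vif)]
    retained <- setdiff(retained, worst)
    dropped <- rbind(dropped, data.frame(
      name = worst, stage = "vif",
      reason = sprintf("VIF = %.3g", max(vif)), stringsAsFactors = FALSE))
    vif <- if (length(retained) >= 2) vifOf(retained) else
      setNames(1, retained)
  }
  structure(list(cor = C, vif = vif, retained = retained, dropped = dropped,
                 rThreshold = rThreshold, vifThreshold = vifThreshold),
            class = "screenReport")
}

#' @export
print.screenReport <- function(x, ...) {
  cat(sprintf("screenReport: %d retained, %d dropped (|r| >= %.2f, VIF >= %g)\n",
              length(x$retained), nrow(x$dropped), x$rThreshold,
              x$vifThreshold))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped))
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("  dropped %s [%s: %s]\n", x$dropped$name[i],
                  x$dropped$stage[i], x$dropped$reason[i]))
  invisible(x)
}

#' Export a screen report as CSV and JSON
#'
#' @param report a \code{screenReport}.
#' @param stem output path stem; writes \code{<stem>.csv} (dropped table)
#'   and \code{<stem>.json} (full report).
#' @return Invisibly, the written paths.
#' @export
writeScreenReport <- function(report, stem) {
  csv <- paste0(stem, ".csv"); js <- paste0(stem, ".json")
  status <- data.frame(
    name = c(report$retained, report$dropped$name),
    status = c(rep("retained", length(report$retained)),
               rep("dropped", nrow(report$dropped))),
    reason = c(rep("", length(report$retained)),
               paste(report$dropped$stage, report$dropped$reason, sep = ": ")))
  write.csv(status, csv, row.names = FALSE)
  jsonlite::write_json(list(retained = report$retained,
                            dropped = report$dropped,
                            vif = as.list(report$vif)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
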