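# Feature expansion for the maximum-entropy model. All features are scaled
# to [0, 1]; scaling constants are computed over background-plus-presence
# values and stored so new data expand identically.

FC_SETS <- c(L = "L", LQ = "LQ", H = "H", LQH = "LQH", LQHP = "LQHP",
             LQHPT = "LQHPT")

parseFc <- function(fc) {
  cls <- strsplit(toupper(fc), "")[[1]]
  bad <- setdiff(cls, c("L", "Q", "H", "P", "T"))
  if (length(bad) || length(cls) == 0)
    stop("feature combination must be a non-empty subset of LQHPT")
  unique(cls)
}

#' Expand predictor values into maxent features
#'
#' Builds the design matrices for a feature combination over presence and
#' background samples. Classes: L = min-max scaled variable; Q = scaled
#' square; P = scaled pairwise products; H = forward hinge
#' \eqn{\max(0, x-k)/(\max-k)} at \code{nKnots} evenly spaced interior
#' knots; T = step indicators \eqn{x > k} at the same knots. Scaling uses
#' the range over presences and background jointly. Constant variables get
#' no Q/H/T features (with a warning).
#'
#' @param presValues,bgValues data.frames/matrices of predictor values
#'   (rows = samples, columns = variables, same columns).
#' @param fc feature-combination string, e.g. \code{"LQH"}.
#' @param nKnots hinge/threshold knots per variable (default 30).
#' @return A list of class \code{"featureExpansion"}: \code{defs}
#'   (data.frame: name, class, var1, var2, knot), \code{scaling},
#'   \code{Fpres}, \code{Fbg} (feature matrices in [0,1]), \code{fc},
#'   \code{varNames}.
#' @export
buildFeatures <- function(presValues, bgValues, fc = "LQH", nKnots = 30L) {
  cls <- parseFc(fc)
  presValues <- as.matrix(presValues); bgValues <- as.matrix(bgValues)
  stopifnot(identical(colnames(presValues), colnames(bgValues)))
  vars <- colnames(presValues)
  all <- rbind(presValues, bgValues)
  lo <- apply(all, 2, min); hi <- apply(all, 2, max)
  constant <- hi - lo <= 0
  if (any(constant))
    warning("constant variable(s), Q/H/T features skipped: ",
            paste(vars[constant], collapse = ", "))

  defs <- list(); k <- 0
  addDef <- function(name, class, var1, var2 = NA, knot = NA) {
    k <<- k + 1
    defs[[k]] <<- data.frame(name = name, class = class, var1 = var1,
                             var2 = var2, knot = knot,
                             stringsAsFactors = FALSE)
  }
  for (v in vars) {
    if ("L" %in% cls) addDef(paste0("L_", v), "L", v)
    if (!constant[v]) {
      if ("Q" %in% cls) addDef(paste0("Q_", v), "Q", v)
      if ("H" %in% cls || "T" %in% cls) {
        knots <- lo[v] + seq_len(nKnots) * (hi[v] - lo[v]) / (nKnots + 1)
        if ("H" %in% cls) for (kn in knots)
          addDef(sprintf("H_%s_%.6g", v, kn), "H", v, knot = kn)
        if ("T" %in% cls) for (kn in knots)
          addDef(sprintf("T_%s_%.6g", v, kn), "T", v, knot = kn)
      }
    }
  }
  if ("P" %in% cls && length(vars) >= 2) {
    cmb <- utils::combn(vars, 2)
    for (j in seq_len(ncol(cmb)))
      if (!constant[cmb[1, j]] && !constant[cmb[2, j]])
        addDef(paste0("P_", cmb[1, j], "_x_", cmb[2, j]), "P",
               cmb[1, j], cmb[2, j])
  }
  defs <- do.call(rbind, defs)

  # product scaling needs the product's own range over the pooled sample
  prodRange <- NULL
  pd <- defs[defs$class == "P", , drop = FALSE]
  if (nrow(pd)) {
    prodRange <- lapply(seq_len(nrow(pd)), function(i) {
      pr <- all[, pd$var1[i]] * all[, pd$var2[i]]
      range(pr)
    })
    names(prodRange) <- pd$name
  }
  scaling <- list(lo = lo, hi = hi, prodRange = prodRange)

  fe <- structure(list(defs = defs, scaling = scaling, fc = fc,
                       varNames = vars, nKnots = nKnots),
                  class = "featureExpansion")
  fe$Fpres <- featureMatrix(fe, presValues)
  fe$Fbg <- featureMatrix(fe, bgValues)
  fe
}

#' Evaluate a feature expansion on new data
#'
#' Applies the stored scaling; inputs beyond the training range are clamped
#' so feature values stay in [0, 1].
#'
#' @param fe a \code{featureExpansion}.
#' @param values matrix/data.frame of predictor values.
#' @return Feature matrix (rows = samples, columns = features).
#' @export
featureMatrix <- function(fe, values) {
  values <- as.matrix(values)
  missing <- setdiff(fe$varNames, colnames(values))
  if (length(missing))
    stop("missing variable(s): ", paste(missing, collapse = ", "))
  lo <- fe$scaling$lo; hi <- fe$scaling$hi
  d <- fe$defs
  out <- matrix(0, nrow(values), nrow(d),
                dimnames = list(NULL, d$name))
  clamp01 <- function(z) pmin(pmax(z, 0), 1)
  for (i in seq_len(nrow(d))) {
    v <- d$var1[i]
    x <- values[, v]
    rngv <- hi[v] - lo[v]
    out[, i] <- switch(d$class[i],
      L = if (rngv > 0) clamp01((x - lo[v]) / rngv) else 0,
      Q = {
        sq <- x^2
        sqlo <- min(lo[v]^2, hi[v]^2,
                    if (lo[v] < 0 && hi[v] > 0) 0 else Inf)
        sqhi <- max(lo[v]^2, hi[v]^2)
        clamp01((sq - sqlo) / (sqhi - sqlo))
      },
      H = clamp01((x - d$knot[i]) / (hi[v] - d$knot[i])),
      T = as.numeric(x > d$knot[i]),
      P = {
        pr <- x * values[, d$var2[i]]
        r <- fe$scaling$prodRange[[d$name[i]]]
        if (diff(r) > 0) clamp01((pr - r[1]) / (r[2] - r[1])) else 0
      })
  }
  out
}
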