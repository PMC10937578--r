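# Bundled worked-example tables: published summary values from a national
# conservation assessment of the Chinese fringe tree (Chionanthus retusus)
# — variable importance, habitat-centroid coordinates under climate
# scenarios, and priority/protected area figures. They serve as inputs for
# the arithmetic consistency checks and the documentation examples; the
# underlying occurrence and climate data are not shipped.

caseStudyFile <- function(name) {
  system.file("extdata", name, package = "sdmplanr", mustWork = TRUE)
}

#' Worked-example tables: fringe-tree conservation assessment
#'
#' Summary tables from a published China-wide habitat and conservation
#' assessment of \emph{Chionanthus retusus}:
#' \code{caseStudyImportance()} — percent contribution and permutation
#' importance of the 12 modelling variables;
#' \code{caseStudyCentroids()} — suitable-habitat centroids per climate
#' scenario with the reported shift distances (metres; NA where no
#' single-leg distance was reported);
#' \code{caseStudyAreas()} — priority, overlap, reserve and study-area
#' extents in km^2.
#'
#' @return A data.frame.
#' @export
caseStudyImportance <- function()
  read.csv(caseStudyFile("chionanthus_importance.csv"))

#' @rdname caseStudyImportance
#' @export
caseStudyCentroids <- function()
  read.csv(caseStudyFile("chionanthus_centroids.csv"))

#' @rdname caseStudyImportance
#' @export
caseStudyAreas <- function() {
  df <- read.csv(caseStudyFile("chionanthus_areas.csv"))
  setNames(df$km2, df$quantity)
}
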