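# Occurrence handling: cleaning, 5-km spatial thinning, value extraction
# and CSV round-trips.

#' Clean raw occurrence records
#'
#' Drops rows with missing or out-of-range coordinates (longitude outside
#' [-180, 180], latitude outside [-90, 90]) and collapses exact coordinate
#' duplicates to the first record. Counts of dropped rows are attached as
#' attributes and reported via message.
#'
#' @param raw data.frame with at least columns \code{species},
#'   \code{longitude}, \code{latitude}; an optional \code{source} column is
#'   preserved.
#' @return Cleaned data.frame with attributes \code{nInvalid} and
#'   \code{nDuplicate}. An all-invalid non-empty input is an error.
#' @export
cleanOccurrences <- function(raw) {
  stopifnot(is.data.frame(raw))
  if (nrow(raw) == 0) {
    out <- data.frame(species = character(), longitude = numeric(),
                      latitude = numeric(), source = character())
    attr(out, "nInvalid") <- 0L; attr(out, "nDuplicate") <- 0L
    return(out)
  }
  lon <- suppressWarnings(as.numeric(raw$longitude))
  lat <- suppressWarnings(as.numeric(raw$latitude))
  ok <- !is.na(lon) & !is.na(lat) & lon >= -180 & lon <= 180 &
    lat >= -90 & lat <= 90
  nInvalid <- sum(!ok)
  if (!any(ok)) stop("no valid occurrence records after coordinate checks")
  out <- data.frame(
    species = as.character(raw$species[ok]),
    longitude = lon[ok], latitude = lat[ok],
    source = if ("source" %in% names(raw)) as.character(raw$source[ok])
             else "unknown",
    stringsAsFactors = FALSE)
  dup <- duplicated(out[, c("longitude", "latitude")])
  nDuplicate <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nInvalid") <- nInvalid
  attr(out, "nDuplicate") <- nDuplicate
  if (nInvalid + nDuplicate > 0)
    message(sprintf("dropped %d invalid and %d duplicate record(s)",
                    nInvalid, nDuplicate))
  out
}

#' Spatially thin occurrences to one record per grid cell
#'
#' Bins records into a fixed-origin grid of approximately
#' \code{cellKm} x \code{cellKm} kilometres anchored at (-180, -90): the
#' latitude bin height is \code{cellKm} converted to degrees, and the
#' longitude bin width is scaled by \code{cos(latitude)} of each record.
#' The first record (input order) in each bin is kept, so thinning is
#' deterministic and idempotent.
#'
#' @param occ cleaned occurrence data.frame.
#' @param cellKm thinning cell size in km (default 5).
#' @return Thinned data.frame (subset of rows of \code{occ}).
#' @export
thinOccurrences <- function(occ, cellKm = 5) {
  if (cellKm <= 0) stop("cellKm must be positive")
  if (nrow(occ) == 0) return(occ)
  dLat <- cellKm / KM_PER_DEGREE
  latBin <- floor((occ$latitude + 90) / dLat)
  coslat <- pmax(cos(occ$latitude * pi / 180), 1e-6)
  dLon <- cellKm / (KM_PER_DEGREE * coslat)
  lonBin <- floor((occ$longitude + 180) / dLon)
  keep <- !duplicated(paste(latBin, lonBin))
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract predictor values at point locations
#'
#' Looks up the stack cell containing each point (half-open cells, addressed
#' from the top-left) and returns one row of layer values per retained
#' point. Points off the grid or on nodata cells are excluded with a
#' warning.
#'
#' @param stack a \linkS4class{PredictorStack}.
#' @param points data.frame with \code{longitude} and \code{latitude}.
#' @return data.frame of layer values for the retained points, with
#'   attributes \code{keptRows} (row indices into \code{points}) and
#'   \code{nExcluded}.
#' @export
extractValues <- function(stack, points) {
  tmpl <- stackTemplate(stack)
  rc <- pointToCell(tmpl, points$longitude, points$latitude)
  land <- landMask(stack)
  onGrid <- !is.na(rc[, 1])
  onLand <- onGrid
  onLand[onGrid] <- land[rc[onGrid, , drop = FALSE]]
  nExcluded <- sum(!onLand)
  if (nExcluded > 0)
    warning(sprintf("%d point(s) off-grid or on nodata excluded", nExcluded))
  idx <- which(onLand)
  cells <- (rc[idx, 2] - 1L) * nRows(tmpl) + rc[idx, 1]
  vals <- as.data.frame(stackValues(stack, cells))
  attr(vals, "keptRows") <- idx
  attr(vals, "nExcluded") <- nExcluded
  vals
}

#' Read / write occurrence CSV files
#'
#' Column layout: species, longitude, latitude and an optional source tag.
#'
#' @param path CSV file path.
#' @return \code{readOccurrences} returns a data.frame.
#' @export
readOccurrences <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname readOccurrences
#' @param occ occurrence data.frame.
#' @export
writeOccurrences <- function(occ, path) {
  write.csv(occ, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
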