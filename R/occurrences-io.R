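#' @include ascii-grid.R
NULL

#' Read occurrence records from a CSV file
#'
#' Rows with unparseable coordinates or coordinates outside
#' [-180, 180] x [-90, 90] are dropped and counted; exact duplicates are kept
#' (deduplication is a separate, explicit cleaning step).
#'
#' @param path CSV file with a header row.
#' @param lonCol,latCol names of the longitude and latitude columns.
#' @param sourceCol optional name of a source-tag column.
#' @return an \linkS4class{Occurrences} object; the number and row indices of
#'   dropped rows are attached as attribute \code{"dropped"}.
#' @export
readOccurrences <- function(path, lonCol = "lon", latCol = "lat",
                            sourceCol = NULL) {
  if (!file.exists(path)) ncStop(sprintf("file not found: %s", path),
                                 class = "nichecast_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  for (col in c(lonCol, latCol, sourceCol))
    if (!col %in% names(df))
      ncStop(sprintf("column '%s' not found in %s", col, path))
  lon <- suppressWarnings(as.numeric(df[[lonCol]]))
  lat <- suppressWarnings(as.numeric(df[[latCol]]))
  bad <- !is.finite(lon) | !is.finite(lat) |
    lon < -180 | lon > 180 | lat < -90 | lat > 90
  src <- if (is.null(sourceCol)) rep("csv", nrow(df))
         else as.character(df[[sourceCol]])
  src[!nzchar(src) | is.na(src)] <- "unknown"
  occ <- occurrences(lon[!bad], lat[!bad], src[!bad])
  attr(occ, "dropped") <- list(n = sum(bad), rows = which(bad))
  occ
}
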