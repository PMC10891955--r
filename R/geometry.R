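#' @include AllGenerics.R
NULL

#' Construct a grid geometry
#'
#' @param nrow,ncol grid dimensions; row 1 is the northernmost row.
#' @param xOrigin,yOrigin map coordinates of the north-west corner (west edge
#'   of column 1, north edge of row 1).
#' @param cellSize cell edge length, positive.
#' @param crs free-text coordinate-system label.
#' @return a \linkS4class{GridGeometry}.
#' @export
#' @examples
#' gridGeometry(10, 10, xOrigin = 0, yOrigin = 10, cellSize = 1)
gridGeometry <- function(nrow, ncol, xOrigin = 0, yOrigin = nrow * cellSize,
                         cellSize = 1, crs = "unspecified") {
  new("GridGeometry", nrow = as.integer(nrow), ncol = as.integer(ncol),
      xOrigin = as.numeric(xOrigin), yOrigin = as.numeric(yOrigin),
      cellSize = as.numeric(cellSize), crs = crs)
}

#' Construct an environmental grid from band matrices
#'
#' @param geometry a \linkS4class{GridGeometry}.
#' @param bands named list of numeric matrices (one per band); NA entries are
#'   folded into the shared nodata mask (union over bands).
#' @param mask optional additional logical nodata matrix.
#' @return an \linkS4class{EnvGrid}.
#' @export
envGrid <- function(geometry, bands, mask = NULL) {
  if (!length(bands)) ncStop("at least one band required")
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    ncStop("bands must be named")
  d <- c(geometry@nrow, geometry@ncol)
  union <- if (is.null(mask)) matrix(FALSE, d[1], d[2]) else mask
  values <- array(NA_real_, c(d, length(bands)))
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    if (!identical(dim(b), d))
      ncStop(sprintf("band '%s' does not match the grid geometry",
                     names(bands)[i]), class = "nichecast_alignment_error")
    union <- union | !is.finite(b)
    values[, , i] <- b
  }
  for (i in seq_along(bands)) values[, , i][union] <- NA_real_
  new("EnvGrid", geometry = geometry, values = values,
      bandNames = names(bands), mask = union)
}

#' Construct an occurrence set
#'
#' @param lon,lat numeric coordinate vectors.
#' @param source source tags (recycled).
#' @return an \linkS4class{Occurrences} object.
#' @export
occurrences <- function(lon, lat, source = "unknown") {
  new("Occurrences", records = data.frame(
    lon = as.numeric(lon), lat = as.numeric(lat),
    source = rep_len(as.character(source), length(lon)),
    stringsAsFactors = FALSE))
}

#' Map coordinates of every cell center
#'
#' @param geometry a \linkS4class{GridGeometry}.
#' @return data.frame with \code{row}, \code{col}, \code{x}, \code{y}.
#' @export
cellCenters <- function(geometry) {
  g <- geometry
  rows <- rep(seq_len(g@nrow), times = g@ncol)
  cols <- rep(seq_len(g@ncol), each = g@nrow)
  data.frame(row = rows, col = cols,
             x = g@xOrigin + (cols - 0.5) * g@cellSize,
             y = g@yOrigin - (rows - 0.5) * g@cellSize)
}

#' Assign occurrence records to grid cells
#'
#' Annotates each record with the (row, col) of the cell containing it under
#' the half-open convention: a point on a cell's west or north edge belongs
#' to that cell. Points outside the grid are flagged off-grid, not dropped.
#'
#' @param occ an \linkS4class{Occurrences} object.
#' @param geometry a \linkS4class{GridGeometry}.
#' @return the occurrences with \code{row}, \code{col} and \code{offGrid}
#'   columns filled in.
#' @export
locateCells <- function(occ, geometry) {
  df <- occ@records
  g <- geometry
  col <- floor((df$lon - g@xOrigin) / g@cellSize) + 1
  row <- floor((g@yOrigin - df$lat) / g@cellSize) + 1
  # points exactly on the south/east outer edge fall outside under the
  # half-open rule
  off <- col < 1 | col > g@ncol | row < 1 | row > g@nrow
  df$row <- ifelse(off, NA_integer_, as.integer(row))
  df$col <- ifelse(off, NA_integer_, as.integer(col))
  df$offGrid <- off
  new("Occurrences", records = df)
}

# Internal: values of all bands at located records; drops nothing.
extractAtRecords <- function(grid, occ) {
  df <- occ@records
  if (is.null(df$row)) ncStop("records must be located first (locateCells)")
  out <- matrix(NA_real_, nrow(df), length(grid@bandNames),
                dimnames = list(NULL, grid@bandNames))
  ok <- !df$offGrid
  for (b in seq_along(grid@bandNames)) {
    m <- grid@values[, , b]
    out[ok, b] <- m[cbind(df$row[ok], df$col[ok])]
  }
  out
}

# Internal: matrix [ncell_valid x nband] of band values on non-nodata cells,
# with the (row, col) index of each.
validCellTable <- function(grid) {
  ok <- !grid@mask
  idx <- which(ok, arr.ind = TRUE)
  vals <- vapply(seq_along(grid@bandNames),
                 function(b) grid@values[, , b][ok], numeric(sum(ok)))
  colnames(vals) <- grid@bandNames
  list(index = idx, values = vals)
}
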