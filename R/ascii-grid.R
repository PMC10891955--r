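#' @include geometry.R
NULL

# ESRI ASCII grid ("Arc/Info ASCII") reader/writer. The header carries the
# lower-left corner; internally the geometry is anchored at the north-west
# corner, so yOrigin = yllcorner + nrows * cellsize.

parseAsciiHeader <- function(lines, path) {
  header <- list()
  i <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      header[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(header)))
    ncStop(sprintf("'%s' is not an ESRI ASCII grid (missing header keys)",
                   path))
  header$nlines <- i
  header
}

#' Read a single-band ESRI ASCII grid
#'
#' @param path file path to a \code{.asc} file.
#' @return list with \code{geometry} (\linkS4class{GridGeometry}),
#'   \code{values} (matrix, NA on nodata) and \code{nodata} (the sentinel).
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) ncStop(sprintf("file not found: %s", path),
                                 class = "nichecast_io_error")
  lines <- readLines(path, n = 7)
  h <- parseAsciiHeader(lines, path)
  nodata <- if (!is.null(h$nodata_value)) h$nodata_value else -9999
  vals <- scan(path, what = numeric(), skip = h$nlines, quiet = TRUE)
  if (length(vals) != h$nrows * h$ncols)
    ncStop(sprintf("'%s': expected %d values, found %d", path,
                   h$nrows * h$ncols, length(vals)))
  m <- matrix(vals, nrow = h$nrows, ncol = h$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  geom <- gridGeometry(h$nrows, h$ncols, xOrigin = h$xllcorner,
                       yOrigin = h$yllcorner + h$nrows * h$cellsize,
                       cellSize = h$cellsize)
  list(geometry = geom, values = m, nodata = nodata)
}

#' Write a single-band ESRI ASCII grid
#'
#' Values are written at full double precision so a write/read round trip is
#' exact; NA cells are written as the nodata sentinel.
#'
#' @param values numeric matrix (row 1 = northernmost row).
#' @param geometry a \linkS4class{GridGeometry}.
#' @param path output file path.
#' @param nodata nodata sentinel written to the header.
#' @return the path, invisibly.
#' @export
writeAsciiGrid <- function(values, geometry, path, nodata = -9999) {
  g <- geometry
  con <- tryCatch(file(path, "w"), error = function(e)
    ncStop(sprintf("cannot open '%s' for writing", path),
           class = "nichecast_io_error"))
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g@ncol),
    sprintf("nrows %d", g@nrow),
    sprintf("xllcorner %.10f", g@xOrigin),
    sprintf("yllcorner %.10f", g@yOrigin - g@nrow * g@cellSize),
    sprintf("cellsize %.10f", g@cellSize),
    sprintf("NODATA_value %g", nodata)), con)
  v <- values
  v[!is.finite(v)] <- nodata
  writeLines(apply(v, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " ")), con)
  invisible(path)
}

sameGeometry <- function(a, b, tol = 1e-9) {
  a@nrow == b@nrow && a@ncol == b@ncol &&
    abs(a@xOrigin - b@xOrigin) <= tol &&
    abs(a@yOrigin - b@yOrigin) <= tol &&
    abs(a@cellSize - b@cellSize) <= tol
}

#' Read an aligned raster stack into an EnvGrid
#'
#' All files must share one grid geometry (identical shape, origins and cell
#' size within 1e-9); the nodata mask of the stack is the union of each
#' file's nodata cells.
#'
#' @param paths character vector of ESRI ASCII grid files, one band each.
#' @param bandNames band identifiers in file order; defaults to file stems.
#' @return an \linkS4class{EnvGrid}.
#' @export
readEnvGrid <- function(paths, bandNames = NULL) {
  if (!length(paths)) ncStop("at least one raster file required")
  if (is.null(bandNames))
    bandNames <- tools::file_path_sans_ext(basename(paths))
  if (anyDuplicated(bandNames))
    ncStop("duplicate band names")
  if (length(bandNames) != length(paths))
    ncStop("one band name per file required")
  first <- readAsciiGrid(paths[1])
  bands <- list(first$values)
  for (i in seq_along(paths)[-1]) {
    b <- readAsciiGrid(paths[i])
    if (!sameGeometry(first$geometry, b$geometry))
      ncStop(sprintf("'%s' is not aligned with '%s'", paths[i], paths[1]),
             class = "nichecast_alignment_error")
    bands[[i]] <- b$values
  }
  names(bands) <- bandNames
  envGrid(first$geometry, bands)
}

#' Write an EnvGrid as one ESRI ASCII grid per band
#'
#' @param grid an \linkS4class{EnvGrid}.
#' @param directory output directory (created if missing).
#' @param format only \code{"ascii_grid"} is supported.
#' @return named character vector of file paths.
#' @export
writeEnvGrid <- function(grid, directory, format = "ascii_grid") {
  format <- match.arg(format, "ascii_grid")
  if (!length(grid@bandNames)) ncStop("grid has no bands")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    ncStop(sprintf("cannot create directory '%s'", directory),
           class = "nichecast_io_error")
  paths <- file.path(directory, paste0(grid@bandNames, ".asc"))
  for (i in seq_along(paths)) {
    v <- grid@values[, , i]
    v[grid@mask] <- NA_real_
    writeAsciiGrid(v, grid@geometry, paths[i])
  }
  stats::setNames(paths, grid@bandNames)
}
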