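#' @include fixtures.R
NULL

prepReport <- function(stage, nIn, keptIdx, droppedIdx) {
  structure(list(stage = stage, input = nIn, retained = length(keptIdx),
                 dropped = length(droppedIdx), droppedRows = droppedIdx),
            class = "prepReport")
}

#' @export
print.prepReport <- function(x, ...) {
  cat(sprintf("prep stage '%s': %d in, %d retained, %d dropped\n",
              x$stage, x$input, x$retained, x$dropped))
  invisible(x)
}

#' Collapse exact coordinate duplicates
#'
#' Records with identical (lon, lat) are collapsed to the first occurrence in
#' input order; coordinates differing at any digit are distinct (no fuzzy
#' matching).
#'
#' @param occ an \linkS4class{Occurrences} object.
#' @return list with \code{occurrences} and a \code{report}.
#' @export
deduplicate <- function(occ) {
  df <- occ@records
  dup <- duplicated(df[, c("lon", "lat")])
  out <- new("Occurrences", records = df[!dup, , drop = FALSE])
  list(occurrences = out,
       report = prepReport("deduplicate", nrow(df), which(!dup), which(dup)))
}

#' Remove records off the grid or on nodata cells
#'
#' Implements the "records in the sea" rule as removal only: a record whose
#' cell carries no environmental data (the nodata mask is the land/validity
#' proxy) is dropped and reported; coordinates are never adjusted.
#'
#' @param occ located \linkS4class{Occurrences} (see
#'   \code{\link{locateCells}}); if not yet located, they are located against
#'   the grid first.
#' @param grid an \linkS4class{EnvGrid}.
#' @return list with \code{occurrences} and a \code{report}.
#' @export
maskFilter <- function(occ, grid) {
  if (is.null(occ@records$row)) occ <- locateCells(occ, grid@geometry)
  df <- occ@records
  bad <- df$offGrid
  onGrid <- which(!bad)
  if (length(onGrid))
    bad[onGrid] <- grid@mask[cbind(df$row[onGrid], df$col[onGrid])]
  out <- new("Occurrences", records = df[!bad, , drop = FALSE])
  list(occurrences = out,
       report = prepReport("maskFilter", nrow(df), which(!bad), which(bad)))
}

#' Spatially thin records to one per grid cell
#'
#' Ensures each cell holds at most one record; within an occupied cell the
#' retained record is chosen uniformly at random under the given seed.
#' Idempotent: a thinned set passes through unchanged.
#'
#' @param occ located \linkS4class{Occurrences}.
#' @param geometry a \linkS4class{GridGeometry} (used to locate if needed).
#' @param seed integer seed for the within-cell choice.
#' @return list with \code{occurrences} and a \code{report}.
#' @export
thinOnePerCell <- function(occ, geometry, seed) {
  if (missing(seed)) ncStop("seed is required")
  if (is.null(occ@records$row)) occ <- locateCells(occ, geometry)
  df <- occ@records
  if (any(df$offGrid)) ncStop("thin requires all records on-grid; run maskFilter first")
  cell <- paste(df$row, df$col)
  keep <- withSeed(seed, {
    unlist(lapply(split(seq_len(nrow(df)), cell), function(ix) {
      if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  out <- new("Occurrences", records = df[keep, , drop = FALSE])
  list(occurrences = out,
       report = prepReport("thin", nrow(df), keep,
                           setdiff(seq_len(nrow(df)), keep)))
}

#' Kernel-density sampling-bias surface
#'
#' Gaussian kernel density of the presence cell centers evaluated at every
#' cell center, rescaled to maximum 1; nodata cells get weight 0. The
#' default bandwidth is Silverman's rule of thumb applied per coordinate
#' axis to the presence cell-center coordinates.
#'
#' @param occ located \linkS4class{Occurrences}.
#' @param geometry a \linkS4class{GridGeometry}.
#' @param bandwidth optional numeric of length 1 or 2 (x and y bandwidth in
#'   map units).
#' @param mask optional logical nodata matrix to zero out.
#' @return a \linkS4class{BiasSurface}.
#' @export
kernelBiasSurface <- function(occ, geometry, bandwidth = NULL, mask = NULL) {
  if (is.null(occ@records$row)) occ <- locateCells(occ, geometry)
  df <- occ@records[!occ@records$offGrid, , drop = FALSE]
  if (!nrow(df)) ncStop("no usable records on the grid")
  g <- geometry
  px <- g@xOrigin + (df$col - 0.5) * g@cellSize
  py <- g@yOrigin - (df$row - 0.5) * g@cellSize
  silverman <- function(v) {
    n <- length(v)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) s <- g@cellSize
    1.06 * s * n^(-1 / 5)
  }
  if (is.null(bandwidth)) bandwidth <- c(silverman(px), silverman(py))
  bandwidth <- rep_len(bandwidth, 2)
  cx <- g@xOrigin + (seq_len(g@ncol) - 0.5) * g@cellSize
  cy <- g@yOrigin - (seq_len(g@nrow) - 0.5) * g@cellSize
  gx <- exp(-0.5 * (outer(cx, px, "-") / bandwidth[1])^2)  # ncol x npts
  gy <- exp(-0.5 * (outer(cy, py, "-") / bandwidth[2])^2)  # nrow x npts
  w <- gy %*% t(gx)                                        # nrow x ncol
  if (!is.null(mask)) w[mask] <- 0
  mx <- max(w)
  if (mx > 0) w <- w / mx
  new("BiasSurface", geometry = g, weights = w, normalization = "max1")
}

#' Sample background cells
#'
#' Draws \code{n} distinct non-nodata cells with probability proportional to
#' the bias weight (uniform when no bias surface is given). If \code{n}
#' exceeds the available cells, all cells are returned with a warning.
#'
#' @param grid an \linkS4class{EnvGrid}.
#' @param n number of background cells (default 10000, the conventional
#'   presence-background default).
#' @param bias optional \linkS4class{BiasSurface}.
#' @param seed integer seed.
#' @return data.frame with \code{row}, \code{col}, \code{x}, \code{y} of the
#'   sampled cell centers.
#' @export
sampleBackground <- function(grid, n = 10000, bias = NULL, seed) {
  if (missing(seed)) ncStop("seed is required")
  if (n < 1) ncStop("n must be at least 1")
  ok <- !grid@mask
  w <- matrix(as.numeric(ok), nrow(ok), ncol(ok))
  if (!is.null(bias)) {
    if (!sameGeometry(grid@geometry, bias@geometry))
      ncStop("bias surface geometry mismatch",
             class = "nichecast_alignment_error")
    w <- w * bias@weights
  }
  avail <- which(w > 0)
  if (!length(avail)) ncStop("no valid cells to sample")
  if (n >= length(avail)) {
    if (n > length(avail))
      ncWarn(sprintf("requested %d background cells, only %d available", n,
                     length(avail)))
    drawn <- avail
  } else {
    drawn <- withSeed(seed, avail[sample.int(length(avail), n,
                                             prob = w[avail])])
  }
  g <- grid@geometry
  row <- (drawn - 1) %% g@nrow + 1
  col <- (drawn - 1) %/% g@nrow + 1
  data.frame(row = row, col = col,
             x = g@xOrigin + (col - 0.5) * g@cellSize,
             y = g@yOrigin - (row - 0.5) * g@cellSize)
}
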