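#' @include AllClasses.R
NULL

#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))

#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))

#' @export
setGeneric("bandValues", function(x, band) standardGeneric("bandValues"))

#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @export
setGeneric("suitabilityValues", function(x) standardGeneric("suitabilityValues"))

#' @export
setGeneric("classValues", function(x) standardGeneric("classValues"))

#' Accessors for grid containers
#'
#' \code{geometry} returns the \linkS4class{GridGeometry}; \code{bandNames}
#' the band identifiers; \code{nodataMask} the logical nodata matrix;
#' \code{bandValues} one band as a matrix; \code{records} the occurrence
#' data.frame; \code{suitabilityValues} / \code{classValues} the per-cell
#' surfaces of suitability and classified maps.
#'
#' @param x the object.
#' @param band band name or index.
#' @name accessors
#' @aliases geometry bandNames nodataMask bandValues records
#'   suitabilityValues classValues
NULL

setMethod("geometry", "EnvGrid", function(x) x@geometry)
setMethod("geometry", "SuitabilityMap", function(x) x@geometry)
setMethod("geometry", "ClassifiedMap", function(x) x@geometry)
setMethod("geometry", "BiasSurface", function(x) x@geometry)
setMethod("bandNames", "EnvGrid", function(x) x@bandNames)
setMethod("nodataMask", "EnvGrid", function(x) x@mask)
setMethod("nodataMask", "SuitabilityMap", function(x) x@mask)
setMethod("bandValues", "EnvGrid", function(x, band) {
  if (is.character(band)) {
    i <- match(band, x@bandNames)
    if (is.na(i)) ncStop(sprintf("unknown band '%s'", band))
  } else i <- band
  x@values[, , i]
})
setMethod("records", "Occurrences", function(x) x@records)
setMethod("suitabilityValues", "SuitabilityMap", function(x) x@values)
setMethod("classValues", "ClassifiedMap", function(x) x@classes)

setMethod("show", "GridGeometry", function(object) {
  cat(sprintf("GridGeometry: %d x %d cells, cell size %g, NW corner (%g, %g), crs '%s'\n",
              object@nrow, object@ncol, object@cellSize,
              object@xOrigin, object@yOrigin, object@crs))
})

setMethod("show", "EnvGrid", function(object) {
  cat(sprintf("EnvGrid: %d band(s) on %d x %d grid (%d nodata cells)\n",
              length(object@bandNames), object@geometry@nrow,
              object@geometry@ncol, sum(object@mask)))
  cat("  bands:", paste(object@bandNames, collapse = ", "), "\n")
})

setMethod("show", "Occurrences", function(object) {
  df <- object@records
  cat(sprintf("Occurrences: %d record(s)", nrow(df)))
  if ("offGrid" %in% names(df))
    cat(sprintf(", %d off-grid", sum(df$offGrid)))
  cat("\n")
})

setMethod("show", "BiasSurface", function(object) {
  cat(sprintf("BiasSurface: %d x %d grid, normalization '%s', max weight %g\n",
              object@geometry@nrow, object@geometry@ncol,
              object@normalization, max(object@weights)))
})

setMethod("show", "SuitabilityMap", function(object) {
  v <- object@values[!object@mask]
  cat(sprintf("SuitabilityMap ('%s', %s): %d x %d grid, P in [%.3f, %.3f]\n",
              object@label, object@transform, object@geometry@nrow,
              object@geometry@ncol,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "ClassifiedMap", function(object) {
  counts <- classCounts(object)
  cat(sprintf("ClassifiedMap ('%s'): mtsps = %.4f\n", object@label,
              object@thresholds[["mtsps"]]))
  print(counts)
})

setMethod("show", "MaxEntModel", function(object) {
  cat(sprintf("MaxEntModel: %d feature(s) over %d variable(s), %d nonzero coefficient(s)\n",
              length(object@beta), length(object@varNames),
              sum(object@beta != 0)))
  cat(sprintf("  regularized training gain %.4f; entropy %.4f; %s after %d pass(es)\n",
              object@gain, object@entropy,
              if (object@converged) "converged" else "NOT converged",
              object@passes))
})
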