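#' @include utils.R
NULL

#' Grid geometry of an aligned raster stack
#'
#' Describes a regular raster grid: row 1 / column 1 is the north-west cell,
#' cell membership uses half-open intervals \code{[edge, edge + cellSize)},
#' and \code{xOrigin}/\code{yOrigin} are the map coordinates of the grid's
#' north-west corner (west edge, north edge).
#'
#' @slot nrow,ncol positive integers, grid dimensions.
#' @slot xOrigin,yOrigin numeric, north-west corner coordinates.
#' @slot cellSize positive numeric, cell edge length (degrees or metres).
#' @slot crs free-text label of the coordinate reference system.
#' @exportClass GridGeometry
setClass("GridGeometry",
  representation(nrow = "integer", ncol = "integer",
                 xOrigin = "numeric", yOrigin = "numeric",
                 cellSize = "numeric", crs = "character"),
  validity = function(object) {
    msg <- character()
    if (object@nrow < 1L || object@ncol < 1L)
      msg <- c(msg, "grid must have at least one cell")
    if (!is.finite(object@cellSize) || object@cellSize <= 0)
      msg <- c(msg, "cellSize must be positive")
    if (!is.finite(object@xOrigin) || !is.finite(object@yOrigin))
      msg <- c(msg, "origin coordinates must be finite")
    if (length(msg)) msg else TRUE
  })

#' Multi-band environmental raster stack
#'
#' Holds one or more environmental surfaces ("bands", e.g. bioclimatic
#' variables bio1..bio20) on a single shared \linkS4class{GridGeometry} with
#' one shared nodata mask: a cell missing any variable is unusable for
#' modelling, so the mask is the union over bands.
#'
#' @slot geometry a \linkS4class{GridGeometry}.
#' @slot values numeric array \code{[nrow, ncol, nband]}.
#' @slot bandNames unique band identifiers, in storage order.
#' @slot mask logical matrix, \code{TRUE} = nodata.
#' @exportClass EnvGrid
setClass("EnvGrid",
  representation(geometry = "GridGeometry", values = "array",
                 bandNames = "character", mask = "matrix"),
  validity = function(object) {
    g <- object@geometry
    d <- dim(object@values)
    msg <- character()
    if (length(d) != 3L)
      msg <- c(msg, "values must be a 3-d array [nrow, ncol, nband]")
    else {
      if (d[1] != g@nrow || d[2] != g@ncol)
        msg <- c(msg, "values dimensions disagree with geometry")
      if (d[3] != length(object@bandNames))
        msg <- c(msg, "number of bands disagrees with bandNames")
    }
    if (anyDuplicated(object@bandNames))
      msg <- c(msg, "bandNames must be unique")
    if (!identical(dim(object@mask), d[1:2]))
      msg <- c(msg, "mask dimensions disagree with values")
    else if (length(d) == 3L && d[3] > 0 && any(!object@mask)) {
      ok <- !object@mask
      for (b in seq_len(d[3])) {
        if (!all(is.finite(object@values[, , b][ok]))) {
          msg <- c(msg,
                   "non-nodata cells must hold finite values in all bands")
          break
        }
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Presence occurrence records
#'
#' A set of longitude/latitude records with a source tag. After
#' \code{\link{locateCells}} each record additionally carries the grid cell
#' (row, col) it falls in, or an off-grid flag.
#'
#' @slot records data.frame with columns \code{lon}, \code{lat},
#'   \code{source}, and optionally \code{row}, \code{col}, \code{offGrid}.
#' @exportClass Occurrences
setClass("Occurrences",
  representation(records = "data.frame"),
  validity = function(object) {
    df <- object@records
    msg <- character()
    if (!all(c("lon", "lat", "source") %in% names(df)))
      msg <- c(msg, "records must have lon, lat and source columns")
    else {
      if (nrow(df) && (any(df$lon < -180 | df$lon > 180) ||
                       any(df$lat < -90 | df$lat > 90)))
        msg <- c(msg, "coordinates out of range")
      if (nrow(df) && any(!nzchar(as.character(df$source))))
        msg <- c(msg, "source tags must be non-empty")
    }
    if (length(msg)) msg else TRUE
  })

#' Kernel-density sampling-bias surface
#'
#' Per-cell nonnegative survey-effort weights on a grid; used to draw
#' background points with the same spatial bias as the presences.
#'
#' @slot geometry a \linkS4class{GridGeometry}.
#' @slot weights nonnegative numeric matrix; nodata cells are 0.
#' @slot normalization how the surface was scaled (e.g. "max1").
#' @exportClass BiasSurface
setClass("BiasSurface",
  representation(geometry = "GridGeometry", weights = "matrix",
                 normalization = "character"),
  validity = function(object) {
    w <- object@weights
    msg <- character()
    if (!identical(dim(w), c(object@geometry@nrow, object@geometry@ncol)))
      msg <- c(msg, "weights dimensions disagree with geometry")
    if (any(w < 0, na.rm = TRUE)) msg <- c(msg, "weights must be nonnegative")
    if (!any(w > 0, na.rm = TRUE))
      msg <- c(msg, "at least one weight must be positive")
    if (length(msg)) msg else TRUE
  })

#' Continuous habitat-suitability surface
#'
#' Per-cell suitability index P. For the cloglog and logistic transforms P
#' lies in [0, 1] (0 = unsuitable, 1 = optimal); for the raw transform the
#' values are the relative occurrence probabilities themselves.
#'
#' @slot geometry a \linkS4class{GridGeometry}.
#' @slot values numeric matrix of P (NA on nodata cells).
#' @slot mask logical matrix, \code{TRUE} = nodata.
#' @slot transform one of "raw", "cloglog", "logistic".
#' @slot label free-text tag (e.g. scenario name).
#' @exportClass SuitabilityMap
setClass("SuitabilityMap",
  representation(geometry = "GridGeometry", values = "matrix",
                 mask = "matrix", transform = "character",
                 label = "character"),
  validity = function(object) {
    msg <- character()
    d <- c(object@geometry@nrow, object@geometry@ncol)
    if (!identical(dim(object@values), d) || !identical(dim(object@mask), d))
      msg <- c(msg, "values/mask dimensions disagree with geometry")
    else {
      v <- object@values[!object@mask]
      if (object@transform %in% c("cloglog", "logistic") &&
          length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
        msg <- c(msg, "cloglog/logistic values must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' Four-class suitability map
#'
#' Partition of a suitability surface into unsuitable / low / medium / high
#' classes: unsuitable P <= t, low t < P <= 0.4, medium 0.4 < P <= 0.6, high
#' P > 0.6, where t is the sensitivity-plus-specificity threshold.
#'
#' @slot geometry a \linkS4class{GridGeometry}.
#' @slot classes integer matrix with codes 0=unsuitable, 1=low, 2=medium,
#'   3=high, NA = nodata.
#' @slot thresholds named numeric: \code{mtsps}, \code{low}, \code{medium}.
#' @slot label free-text tag.
#' @exportClass ClassifiedMap
setClass("ClassifiedMap",
  representation(geometry = "GridGeometry", classes = "matrix",
                 thresholds = "numeric", label = "character"),
  validity = function(object) {
    msg <- character()
    d <- c(object@geometry@nrow, object@geometry@ncol)
    if (!identical(dim(object@classes), d))
      msg <- c(msg, "classes dimensions disagree with geometry")
    cl <- object@classes[!is.na(object@classes)]
    if (length(cl) && !all(cl %in% 0:3))
      msg <- c(msg, "class codes must be 0..3")
    if (!all(c("mtsps", "low", "medium") %in% names(object@thresholds)))
      msg <- c(msg, "thresholds must name mtsps, low and medium")
    if (length(msg)) msg else TRUE
  })

#' Fitted maximum-entropy presence-background model
#'
#' Result of \code{\link{maxentFit}}: feature definitions and their L1
#' penalties, the coefficient vector, the background log-normalizer and
#' entropy of the fitted distribution, the regularized training gain and its
#' per-variable attribution ledger, and the training metadata needed to
#' reproduce predictions (variable scaling, presence means, config echo).
#'
#' @slot features data.frame of feature definitions (class, var1, var2, knot,
#'   reverse) plus each feature's penalty weight.
#' @slot beta numeric coefficient vector, one per feature.
#' @slot varNames variables the model was trained on.
#' @slot scaling list with per-variable \code{min} and \code{max} over the
#'   training background (the [0, 1] normalization and clamping range).
#' @slot presMeans per-variable mean over training presences (response-curve
#'   reference point).
#' @slot logZ log of the weighted background normalizer at the fitted
#'   coefficients.
#' @slot entropy entropy H of the fitted distribution over the training
#'   background.
#' @slot gain regularized training gain G (0 for the null model).
#' @slot gainTrace per-pass gain trace of the optimizer.
#' @slot contrib per-variable accumulated gain increments (the percent
#'   contribution ledger).
#' @slot config the \code{\link{maxentConfig}} used.
#' @slot converged logical; \code{FALSE} if the pass limit was hit.
#' @slot passes number of coordinate-descent passes run.
#' @slot nBackground number of background samples used.
#' @slot seed seed recorded at fit time (NA if none supplied).
#' @exportClass MaxEntModel
setClass("MaxEntModel",
  representation(features = "data.frame", beta = "numeric",
                 varNames = "character", scaling = "list",
                 presMeans = "numeric", logZ = "numeric",
                 entropy = "numeric", gain = "numeric",
                 gainTrace = "numeric", contrib = "numeric",
                 config = "list", converged = "logical",
                 passes = "integer", nBackground = "integer",
                 seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@features) != length(object@beta))
      msg <- c(msg, "one coefficient per feature required")
    if (length(object@gain) && object@gain < -1e-8)
      msg <- c(msg, "regularized gain must be nonnegative")
    if (length(msg)) msg else TRUE
  })
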