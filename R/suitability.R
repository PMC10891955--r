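#' @include evaluation.R
NULL

#' Maximum sensitivity-plus-specificity threshold
#'
#' Candidate thresholds are the unique observed scores. At a threshold t,
#' sensitivity is the fraction of presence scores >= t and specificity the
#' fraction of background scores < t. The smallest t maximizing their sum is
#' returned (the deterministic, inclusive tie-break).
#'
#' @param presenceScores,backgroundScores numeric score vectors (typically
#'   pooled out-of-fold cross-validation predictions).
#' @param source free-text provenance tag stored in the result.
#' @return a \code{thresholdResult}: list with \code{mtsps},
#'   \code{sensitivity}, \code{specificity}, \code{source}.
#' @export
mtspsThreshold <- function(presenceScores, backgroundScores,
                           source = "pooled out-of-fold") {
  if (!length(presenceScores) || !length(backgroundScores))
    ncStop("both score lists must be non-empty")
  cand <- sort(unique(c(presenceScores, backgroundScores)))
  np <- length(presenceScores)
  nb <- length(backgroundScores)
  sens <- 1 - (findInterval(cand, sort(presenceScores),
                            left.open = TRUE) ) / np
  spec <- findInterval(cand, sort(backgroundScores),
                       left.open = TRUE) / nb
  total <- sens + spec
  best <- which(total >= max(total) - 1e-12)[1]
  structure(list(mtsps = cand[best], sensitivity = sens[best],
                 specificity = spec[best], source = source),
            class = "thresholdResult")
}

#' @export
print.thresholdResult <- function(x, ...) {
  cat(sprintf("MTSPS = %.4f (sensitivity %.3f, specificity %.3f; %s)\n",
              x$mtsps, x$sensitivity, x$specificity, x$source))
  invisible(x)
}

#' Four-class suitability classification
#'
#' Classes follow the left-open / right-closed convention: unsuitable
#' P <= mtsps; low mtsps < P <= 0.4; medium 0.4 < P <= 0.6; high P > 0.6.
#' If mtsps >= 0.4 the low class is structurally empty (allowed; a message
#' is emitted).
#'
#' @param suit a \linkS4class{SuitabilityMap}.
#' @param mtsps threshold in [0, 1] (a number or a \code{thresholdResult}).
#' @param low,medium upper bounds of the low and medium classes.
#' @return a \linkS4class{ClassifiedMap}.
#' @export
classify <- function(suit, mtsps, low = 0.4, medium = 0.6) {
  if (inherits(mtsps, "thresholdResult")) mtsps <- mtsps$mtsps
  if (mtsps < 0 || mtsps > 1) ncStop("mtsps must lie in [0, 1]")
  if (mtsps >= low)
    message(sprintf("mtsps (%.4f) >= %.2f: the low class is empty", mtsps,
                    low))
  P <- suit@values
  cl <- matrix(NA_integer_, nrow(P), ncol(P))
  ok <- !suit@mask & !is.na(P)
  cl[ok] <- ifelse(P[ok] <= mtsps, 0L,
                   ifelse(P[ok] <= low, 1L, ifelse(P[ok] <= medium, 2L, 3L)))
  new("ClassifiedMap", geometry = suit@geometry, classes = cl,
      thresholds = c(mtsps = mtsps, low = low, medium = medium),
      label = suit@label)
}

#' Class cell counts of a classified map
#'
#' @param map a \linkS4class{ClassifiedMap}.
#' @return named integer vector over unsuitable/low/medium/high.
#' @export
classCounts <- function(map) {
  lv <- c("unsuitable", "low", "medium", "high")
  counts <- table(factor(map@classes, levels = 0:3, labels = lv))
  stats::setNames(as.integer(counts), lv)
}

#' Project a fitted model onto a (scenario) grid
#'
#' Prediction with clamping to the training variable ranges by default (the
#' transfer convention: novel climates beyond the training range are held at
#' the range edge rather than extrapolated through the features).
#'
#' @param model a \linkS4class{MaxEntModel}.
#' @param scenarioGrid an \linkS4class{EnvGrid} supplying every model
#'   variable.
#' @param transform output transform (default: model config).
#' @param clamp default TRUE.
#' @param label map label; defaults to the grid's scenario tag if present.
#' @return a \linkS4class{SuitabilityMap}.
#' @export
project <- function(model, scenarioGrid, transform = NULL, clamp = TRUE,
                    label = NULL) {
  if (is.null(label)) {
    label <- attr(scenarioGrid, "scenario")
    if (is.null(label)) label <- "projection"
  }
  maxentPredict(model, scenarioGrid, transform = transform, clamp = clamp,
                label = label)
}

#' Class-change accounting between two classified maps
#'
#' @param a,b \linkS4class{ClassifiedMap}s on identical geometry with
#'   identical nodata pattern.
#' @param cellArea optional per-cell area weight matrix.
#' @return a \code{changeSummary}: list with per-map class \code{counts},
#'   the 4 x 4 \code{transitions} matrix (rows = classes of \code{a},
#'   columns = classes of \code{b}), per-class \code{netChange} in cells,
#'   and, when \code{cellArea} is given, the same in area units.
#' @export
changeSummary <- function(a, b, cellArea = NULL) {
  if (!sameGeometry(a@geometry, b@geometry))
    ncStop("maps are not on the same geometry",
           class = "nichecast_alignment_error")
  okA <- !is.na(a@classes)
  okB <- !is.na(b@classes)
  if (!identical(okA, okB))
    ncStop("maps have different nodata patterns",
           class = "nichecast_alignment_error")
  lv <- c("unsuitable", "low", "medium", "high")
  fa <- factor(a@classes[okA], levels = 0:3, labels = lv)
  fb <- factor(b@classes[okB], levels = 0:3, labels = lv)
  trans <- table(from = fa, to = fb)
  countsA <- table(fa)
  countsB <- table(fb)
  out <- list(counts = rbind(a = as.integer(countsA),
                             b = as.integer(countsB)),
              transitions = unclass(trans),
              netChange = as.integer(countsB) - as.integer(countsA),
              totalCells = sum(okA))
  colnames(out$counts) <- lv
  names(out$netChange) <- lv
  if (!is.null(cellArea)) {
    w <- cellArea[okA]
    out$area <- rbind(
      a = vapply(lv, function(l) sum(w[fa == l]), numeric(1)),
      b = vapply(lv, function(l) sum(w[fb == l]), numeric(1)))
    out$netAreaChange <- out$area["b", ] - out$area["a", ]
  }
  structure(out, class = "changeSummary")
}

#' @export
print.changeSummary <- function(x, ...) {
  cat(sprintf("Class change over %d cells (net, b - a):\n", x$totalCells))
  print(x$netChange)
  invisible(x)
}

#' Write a classified map as an integer ESRI ASCII grid with a JSON legend
#'
#' @param map a \linkS4class{ClassifiedMap}.
#' @param path output \code{.asc} path; the legend lands beside it as
#'   \code{<path>.legend.json}.
#' @return the raster path, invisibly.
#' @export
writeClassifiedMap <- function(map, path) {
  v <- map@classes
  storage.mode(v) <- "double"
  writeAsciiGrid(v, map@geometry, path)
  jsonlite::write_json(
    list(codes = list(unsuitable = 0, low = 1, medium = 2, high = 3),
         thresholds = as.list(map@thresholds), label = map@label),
    paste0(path, ".legend.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
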