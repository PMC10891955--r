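#' @include occurrences-io.R
NULL

# Row-normalized Gaussian smoothing matrix for one axis.
smoothMatrix <- function(n, sdCells) {
  if (sdCells <= 0) return(diag(n))
  K <- exp(-0.5 * (outer(seq_len(n), seq_len(n), "-") / sdCells)^2)
  K / rowSums(K)
}

#' Generate a correlated stack of smooth environmental surfaces
#'
#' Bands are built from independent white-noise fields convolved with a
#' separable Gaussian kernel, then linearly mixed (whitening followed by a
#' Cholesky factor of the target matrix) so that the empirical pairwise
#' correlations over all cells match \code{targetCorr}. The achieved
#' correlation matrix of the final (unit-scaled, possibly floor-clamped)
#' values is attached as attribute \code{"achievedCorr"}, because clamping
#' can perturb the induced correlations.
#'
#' @param geometry a \linkS4class{GridGeometry}.
#' @param nBands number of bands.
#' @param smoothness Gaussian kernel standard deviation in cells.
#' @param targetCorr optional symmetric positive-semi-definite correlation
#'   matrix with unit diagonal; identity if omitted.
#' @param seed integer seed (mandatory: generation is stochastic).
#' @param bandNames band identifiers.
#' @param means,sds per-band affine scaling from z-scores to physical units.
#' @param lowerBound optional per-band floor (e.g. 0 for precipitation).
#' @param nodataBorder width in cells of the nodata border frame.
#' @return an \linkS4class{EnvGrid} with attribute \code{"achievedCorr"}.
#' @export
makeEnvGrid <- function(geometry, nBands, smoothness = 3, targetCorr = NULL,
                        seed, bandNames = paste0("env", seq_len(nBands)),
                        means = 0, sds = 1, lowerBound = -Inf,
                        nodataBorder = 1) {
  g <- geometry
  if (missing(seed)) ncStop("seed is required")
  if (is.null(targetCorr)) targetCorr <- diag(nBands)
  if (!isTRUE(all.equal(targetCorr, t(targetCorr), tolerance = 1e-8)) ||
      any(abs(diag(targetCorr) - 1) > 1e-8))
    ncStop("targetCorr must be symmetric with unit diagonal")
  U <- tryCatch(chol(targetCorr), error = function(e)
    ncStop(paste("targetCorr is not positive semi-definite;",
                 "consider a nearest-PSD repair (e.g. Matrix::nearPD)")))
  means <- rep_len(means, nBands)
  sds <- rep_len(sds, nBands)
  lowerBound <- rep_len(lowerBound, nBands)
  ncell <- g@nrow * g@ncol
  if (ncell <= nBands + 1)
    ncStop("grid too small for the requested number of bands")

  Sr <- smoothMatrix(g@nrow, smoothness)
  Sc <- smoothMatrix(g@ncol, smoothness)
  E <- withSeed(seed, {
    vapply(seq_len(nBands), function(b) {
      as.vector(Sr %*% matrix(rnorm(ncell), g@nrow, g@ncol) %*% t(Sc))
    }, numeric(ncell))
  })
  # exact whitening of the smoothed fields, then Cholesky mixing
  E <- scale(E)
  E <- E %*% backsolve(chol(stats::cov(E)), diag(nBands))
  X <- E %*% U

  mask <- matrix(FALSE, g@nrow, g@ncol)
  if (nodataBorder > 0) {
    b <- seq_len(nodataBorder)
    mask[c(b, g@nrow + 1 - b), ] <- TRUE
    mask[, c(b, g@ncol + 1 - b)] <- TRUE
  }
  bands <- list()
  for (i in seq_len(nBands)) {
    m <- matrix(X[, i] * sds[i] + means[i], g@nrow, g@ncol)
    m[m < lowerBound[i]] <- lowerBound[i]
    bands[[i]] <- m
  }
  names(bands) <- bandNames
  grid <- envGrid(g, bands, mask = mask)
  flat <- vapply(seq_len(nBands), function(i) as.vector(bands[[i]]),
                 numeric(ncell))
  achieved <- stats::cor(flat)
  dimnames(achieved) <- list(bandNames, bandNames)
  attr(grid, "achievedCorr") <- achieved
  grid
}

#' Declare one niche response
#'
#' Shapes available: \code{plateau_unimodal} (suitability 1 on
#' [lower, upper], Gaussian tails outside, tail width 20\% of the plateau
#' span unless overridden), \code{peaked} (Gaussian around \code{peak} with
#' \code{width}), \code{saturating} (0 at 0, smooth rise to 1 at
#' \code{lower}, then stays at 1), and \code{flat}.
#'
#' @param kind response shape.
#' @param lower,upper plateau/rise interval bounds.
#' @param peak,width peak location and Gaussian decay width.
#' @param weight exponent weight in (0, 1].
#' @param tailWidth plateau tail standard deviation override.
#' @return a response definition (list) for \code{\link{nicheSpec}}.
#' @export
nicheResponse <- function(kind = c("plateau_unimodal", "peaked", "saturating",
                                   "flat"),
                          lower = NA, upper = NA, peak = NA, width = NA,
                          weight = 1, tailWidth = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(weight) || weight <= 0 || weight > 1)
    ncStop("weight must lie in (0, 1]")
  if (kind %in% c("plateau_unimodal", "saturating")) {
    if (!is.finite(lower) || !is.finite(upper) || lower > upper)
      ncStop("lower/upper must be finite with lower <= upper")
  }
  if (kind == "peaked" && (!is.finite(peak) || !is.finite(width) || width <= 0))
    ncStop("peaked response needs a finite peak and positive width")
  structure(list(kind = kind, lower = lower, upper = upper, peak = peak,
                 width = width, weight = weight, tailWidth = tailWidth),
            class = "nicheResponse")
}

#' Assemble a niche specification
#'
#' @param ... named \code{\link{nicheResponse}} definitions; names are band
#'   names.
#' @return a named list of responses (class \code{nicheSpec}).
#' @export
#' @examples
#' nicheSpec(temp = nicheResponse("plateau_unimodal", lower = 15, upper = 25))
nicheSpec <- function(...) {
  resp <- list(...)
  if (!length(resp) || is.null(names(resp)) || any(!nzchar(names(resp))))
    ncStop("responses must be named by band")
  if (all(vapply(resp, function(r) r$kind == "flat", logical(1))))
    ncStop("at least one non-flat response required")
  structure(resp, class = "nicheSpec")
}

responseValue <- function(resp, v) {
  switch(resp$kind,
    flat = rep(1, length(v)),
    plateau_unimodal = {
      tw <- if (!is.null(resp$tailWidth)) resp$tailWidth
            else 0.2 * (resp$upper - resp$lower)
      if (!is.finite(tw) || tw <= 0) tw <- 1e-8
      out <- rep(1, length(v))
      out[is.na(v)] <- NA_real_
      lo <- which(v < resp$lower)
      hi <- which(v > resp$upper)
      out[lo] <- exp(-0.5 * ((resp$lower - v[lo]) / tw)^2)
      out[hi] <- exp(-0.5 * ((v[hi] - resp$upper) / tw)^2)
      out
    },
    peaked = exp(-0.5 * ((v - resp$peak) / resp$width)^2),
    saturating = {
      out <- rep(1, length(v))
      out[is.na(v)] <- NA_real_
      out[which(v <= 0)] <- 0
      ramp <- which(v > 0 & v < resp$lower)
      out[ramp] <- sin(0.5 * pi * v[ramp] / resp$lower)^2
      out
    })
}

#' Ground-truth suitability of a planted niche
#'
#' Per cell, the weighted product of the band responses
#' (\code{prod(response^weight)}), rescaled so the maximum over non-nodata
#' cells is 1.
#'
#' @param grid an \linkS4class{EnvGrid}.
#' @param niche a \code{\link{nicheSpec}}.
#' @return a \linkS4class{SuitabilityMap} (transform label \code{"true"}).
#' @export
trueSuitability <- function(grid, niche) {
  missing <- setdiff(names(niche), grid@bandNames)
  if (length(missing))
    ncStop(sprintf("niche bands not in grid: %s",
                   paste(missing, collapse = ", ")))
  g <- grid@geometry
  s <- matrix(1, g@nrow, g@ncol)
  for (band in names(niche)) {
    r <- niche[[band]]
    s <- s * matrix(responseValue(r, as.vector(bandValues(grid, band))),
                    g@nrow, g@ncol)^r$weight
  }
  s[grid@mask] <- NA_real_
  mx <- max(s, na.rm = TRUE)
  if (mx > 0) s <- s / mx
  new("SuitabilityMap", geometry = g, values = s, mask = grid@mask,
      transform = "true", label = "true")
}

#' Sample presence records from a suitability surface
#'
#' Cells are drawn with probability proportional to suitability times an
#' optional bias surface; one record is placed at each drawn cell's center.
#'
#' @param suit a \linkS4class{SuitabilityMap}.
#' @param n number of records.
#' @param biasSurface optional \linkS4class{BiasSurface}.
#' @param seed integer seed.
#' @param replace draw with replacement (default FALSE: distinct cells).
#' @return an \linkS4class{Occurrences} object (source tag "synthetic").
#' @export
sampleOccurrences <- function(suit, n, biasSurface = NULL, seed,
                              replace = FALSE) {
  if (missing(seed)) ncStop("seed is required")
  ok <- !suit@mask & is.finite(suit@values)
  w <- suit@values
  if (!is.null(biasSurface)) {
    if (!sameGeometry(suit@geometry, biasSurface@geometry))
      ncStop("bias surface geometry mismatch",
             class = "nichecast_alignment_error")
    w <- w * biasSurface@weights
  }
  w[!ok] <- 0
  w[is.na(w)] <- 0
  if (all(w == 0)) ncStop("suitability (times bias) is zero everywhere")
  if (!replace && n > sum(w > 0))
    ncStop("n exceeds the number of available cells")
  idx <- which(w > 0)
  drawn <- withSeed(seed, idx[sample.int(length(idx), n, replace = replace,
                                         prob = w[idx])])
  g <- suit@geometry
  row <- (drawn - 1) %% g@nrow + 1
  col <- (drawn - 1) %/% g@nrow + 1
  occurrences(lon = g@xOrigin + (col - 0.5) * g@cellSize,
              lat = g@yOrigin - (row - 0.5) * g@cellSize,
              source = "synthetic")
}

#' Declare a climate scenario perturbation
#'
#' Temperature-like bands are shifted additively; precipitation-like bands
#' are scaled multiplicatively, mirroring warming plus wetting/drying of
#' altered-climate layer sets.
#'
#' @param label scenario label (e.g. "SSP1-2.6-2030").
#' @param add named numeric vector of additive deltas per band.
#' @param mult named numeric vector of positive multiplicative factors.
#' @return a scenario definition (class \code{scenarioSpec}).
#' @export
scenarioSpec <- function(label, add = numeric(), mult = numeric()) {
  if (!nzchar(label)) ncStop("label must be non-empty")
  if (length(add) && is.null(names(add))) ncStop("add must be named by band")
  if (length(mult)) {
    if (is.null(names(mult))) ncStop("mult must be named by band")
    if (any(mult <= 0)) ncStop("multiplicative factors must be positive")
  }
  structure(list(label = label, add = add, mult = mult),
            class = "scenarioSpec")
}

#' Apply a scenario perturbation to an environmental stack
#'
#' @param grid an \linkS4class{EnvGrid}.
#' @param scenario a \code{\link{scenarioSpec}}.
#' @return a perturbed \linkS4class{EnvGrid} (same geometry and mask).
#' @export
applyScenario <- function(grid, scenario) {
  unknown <- setdiff(c(names(scenario$add), names(scenario$mult)),
                     grid@bandNames)
  if (length(unknown))
    ncStop(sprintf("scenario names bands not in grid: %s",
                   paste(unknown, collapse = ", ")))
  out <- grid
  for (band in names(scenario$add)) {
    i <- match(band, grid@bandNames)
    out@values[, , i] <- out@values[, , i] + scenario$add[[band]]
  }
  for (band in names(scenario$mult)) {
    i <- match(band, grid@bandNames)
    out@values[, , i] <- out@values[, , i] * scenario$mult[[band]]
  }
  for (i in seq_along(out@bandNames)) out@values[, , i][out@mask] <- NA_real_
  attr(out, "scenario") <- scenario$label
  out
}

#' Default synthetic study world
#'
#' A 100 x 100 cell world of eight mutually correlated smooth bands with a
#' planted niche on three of them: a unimodal plateau response on the
#' cold-quarter temperature band (optimal 15-25 degrees), a peaked response
#' on wettest-month precipitation (around 200 mm) and a saturating response
#' on driest-month precipitation (rising to its maximum over 50-150 mm).
#' The remaining five bands are correlated nuisance variables. Used as the
#' standard testbed for the whole pipeline.
#'
#' @param seed integer seed.
#' @param nrow,ncol grid dimensions.
#' @param smoothness kernel standard deviation in cells.
#' @return list with \code{grid} (\linkS4class{EnvGrid}), \code{niche}
#'   (\code{\link{nicheSpec}}), \code{suitability}
#'   (\linkS4class{SuitabilityMap}) and \code{bandRoles} (temperature-like /
#'   precipitation-like classification used by scenarios).
#' @export
makeDefaultWorld <- function(seed, nrow = 100, ncol = 100, smoothness = 4) {
  bands <- c("temp_cold", "prec_wet", "prec_dry", "temp_ann", "temp_seas",
             "isotherm", "prec_ann", "elev")
  C <- diag(8)
  dimnames(C) <- list(bands, bands)
  pairs <- rbind(
    c("temp_cold", "temp_ann", 0.85),
    c("temp_cold", "isotherm", 0.45),
    c("temp_cold", "temp_seas", -0.60),
    c("temp_ann", "temp_seas", -0.45),
    c("temp_ann", "elev", -0.50),
    c("temp_cold", "elev", -0.40),
    c("prec_wet", "prec_ann", 0.85),
    c("prec_dry", "prec_ann", 0.55),
    c("prec_wet", "prec_dry", 0.35),
    c("isotherm", "temp_seas", -0.55),
    c("isotherm", "temp_ann", 0.40))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    C[i, j] <- C[j, i] <- as.numeric(pairs[k, 3])
  }
  # center the world on (0, 0) with a cell size keeping coordinates within
  # valid geographic bounds
  cs <- min(1, 120 / nrow, 240 / ncol)
  grid <- makeEnvGrid(
    gridGeometry(nrow, ncol, xOrigin = -ncol * cs / 2,
                 yOrigin = nrow * cs / 2, cellSize = cs),
    nBands = 8, smoothness = smoothness, targetCorr = C, seed = seed,
    bandNames = bands,
    means = c(9, 310, 35, 14, 40, 50, 1200, 500),
    sds = c(12, 180, 60, 9, 20, 15, 600, 400),
    lowerBound = c(-Inf, 0, 0, -Inf, 0, 0, 0, 0))
  niche <- nicheSpec(
    temp_cold = nicheResponse("plateau_unimodal", lower = 15, upper = 25),
    prec_wet = nicheResponse("peaked", peak = 200, width = 150),
    prec_dry = nicheResponse("saturating", lower = 50, upper = 150))
  list(grid = grid, niche = niche,
       suitability = trueSuitability(grid, niche),
       bandRoles = c(temp_cold = "temperature", prec_wet = "precipitation",
                     prec_dry = "precipitation", temp_ann = "temperature",
                     temp_seas = "temperature", isotherm = "temperature",
                     prec_ann = "precipitation", elev = "other"))
}
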