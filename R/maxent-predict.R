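#' @include maxent-fit.R
NULL

# Scale raw variable values with a model's training scaling, optionally
# clamping to the training range first.
scaleForModel <- function(model, values, clamp) {
  vars <- model@varNames
  if (!all(vars %in% colnames(values)))
    ncStop(sprintf("missing variable(s): %s",
                   paste(setdiff(vars, colnames(values)), collapse = ", ")))
  x <- values[, vars, drop = FALSE]
  mn <- model@scaling$min[vars]
  mx <- model@scaling$max[vars]
  if (clamp) {
    lo <- matrix(mn, nrow(x), length(vars), byrow = TRUE)
    hi <- matrix(mx, nrow(x), length(vars), byrow = TRUE)
    x <- pmin(pmax(x, lo), hi)
  }
  s <- sweep(sweep(x, 2, mn, "-"), 2, pmax(mx - mn, 1e-300), "/")
  const <- model@scaling$constant[vars]
  if (any(const)) s[, const] <- 0
  colnames(s) <- vars
  s
}

# Linear predictor eta at raw variable values.
modelEta <- function(model, values, clamp) {
  s <- scaleForModel(model, values, clamp)
  as.vector(featureMatrix(model@features, s) %*% model@beta)
}

#' Predict suitability from a fitted maxent model
#'
#' Raw output is \eqn{q(z) = e^{\eta(z) - \log Z} / n_{bg}}, which sums to 1
#' over the training background; the cloglog transform is
#' \eqn{P = 1 - \exp(-e^{H} q(z))} and the logistic transform
#' \eqn{P = e^{H} q(z) / (1 + e^{H} q(z))}, with \eqn{H} the entropy of the
#' fitted distribution over the training background. With clamping on
#' (default per config), variables are clipped to the training range before
#' feature expansion.
#'
#' @param model a \linkS4class{MaxEntModel}.
#' @param newdata an \linkS4class{EnvGrid} or a numeric matrix with variable
#'   columns.
#' @param transform output transform; defaults to the model config.
#' @param clamp clamp to training ranges; defaults to the model config.
#' @param label label attached to a returned map.
#' @return a \linkS4class{SuitabilityMap} when \code{newdata} is a grid, else
#'   a numeric vector.
#' @export
maxentPredict <- function(model, newdata, transform = NULL, clamp = NULL,
                          label = "prediction") {
  transform <- if (is.null(transform)) model@config$transform
               else match.arg(transform, c("cloglog", "logistic", "raw"))
  clamp <- if (is.null(clamp)) isTRUE(model@config$clamp) else isTRUE(clamp)
  toP <- function(eta) {
    raw <- exp(eta - model@logZ) / model@nBackground
    switch(transform,
           raw = raw,
           cloglog = 1 - exp(-exp(model@entropy) * raw),
           logistic = {
             x <- exp(model@entropy) * raw
             x / (1 + x)
           })
  }
  if (is(newdata, "EnvGrid")) {
    vt <- validCellTable(newdata)
    p <- toP(modelEta(model, vt$values, clamp))
    g <- newdata@geometry
    vals <- matrix(NA_real_, g@nrow, g@ncol)
    vals[vt$index] <- p
    new("SuitabilityMap", geometry = g, values = vals, mask = newdata@mask,
        transform = transform, label = label)
  } else {
    toP(modelEta(model, as.matrix(newdata), clamp))
  }
}

#' Serialize a fitted model to JSON
#'
#' The document carries the feature definitions, coefficients, scaling,
#' normalizer, entropy, config echo and seed -- everything needed to
#' reproduce predictions bit-for-bit via \code{\link{modelFromJSON}}.
#'
#' @param model a \linkS4class{MaxEntModel}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
modelToJSON <- function(model, path) {
  doc <- list(
    features = model@features, beta = model@beta, varNames = model@varNames,
    scaling = list(min = as.list(model@scaling$min),
                   max = as.list(model@scaling$max),
                   constant = as.list(model@scaling$constant)),
    presMeans = as.list(model@presMeans),
    logZ = model@logZ, entropy = model@entropy, gain = model@gain,
    gainTrace = model@gainTrace, contrib = as.list(model@contrib),
    config = model@config[setdiff(names(model@config), "autoCutoffs")],
    converged = model@converged, passes = model@passes,
    nBackground = model@nBackground, seed = model@seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Restore a fitted model from JSON
#'
#' @param path file written by \code{\link{modelToJSON}}.
#' @return a \linkS4class{MaxEntModel}.
#' @export
modelFromJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- doc$config
  cfg$autoCutoffs <- c(quadratic = 10, hinge = 15, threshold = 80,
                       product = 80)
  feats <- as.data.frame(doc$features, stringsAsFactors = FALSE)
  feats$knot <- as.numeric(feats$knot)
  feats$var2 <- as.character(feats$var2)
  new("MaxEntModel", features = feats, beta = as.numeric(doc$beta),
      varNames = as.character(doc$varNames),
      scaling = list(min = unlist(doc$scaling$min),
                     max = unlist(doc$scaling$max),
                     constant = {
                       cst <- unlist(doc$scaling$constant)
                       storage.mode(cst) <- "logical"
                       cst
                     }),
      presMeans = unlist(doc$presMeans), logZ = doc$logZ,
      entropy = doc$entropy, gain = doc$gain,
      gainTrace = as.numeric(doc$gainTrace), contrib = unlist(doc$contrib),
      config = cfg, converged = doc$converged,
      passes = as.integer(doc$passes),
      nBackground = as.integer(doc$nBackground),
      seed = as.numeric(doc$seed))
}
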