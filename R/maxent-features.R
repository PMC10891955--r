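#' @include occurrence-prep.R
NULL

#' Maxent engine configuration
#'
#' @param featureClasses feature classes to consider; with
#'   \code{autoFeatures} the actually enabled set also depends on the
#'   presence count (quadratic from 10 presences, hinge from 15, threshold
#'   and product from 80 -- the conventional auto-feature cutoffs).
#' @param rm regularization multiplier (global scalar on the L1 penalty);
#'   default 1.
#' @param autoFeatures gate feature classes by presence count.
#' @param knots number of threshold/hinge knots per variable, placed at
#'   equally spaced background quantiles.
#' @param maxPasses coordinate-descent pass limit.
#' @param tol convergence tolerance on the penalized gain per pass.
#' @param transform default output transform.
#' @param clamp clip prediction-time values to the training range.
#' @return a config list (class \code{maxentConfig}).
#' @export
maxentConfig <- function(featureClasses = c("linear", "quadratic", "product",
                                            "threshold", "hinge"),
                         rm = 1, autoFeatures = TRUE, knots = 20,
                         maxPasses = 2000, tol = 1e-6,
                         transform = c("cloglog", "logistic", "raw"),
                         clamp = TRUE) {
  featureClasses <- match.arg(featureClasses, several.ok = TRUE)
  if (rm <= 0) ncStop("rm must be positive")
  if (tol <= 0) ncStop("tol must be positive")
  if (knots < 1) ncStop("knots must be at least 1")
  structure(list(featureClasses = featureClasses, rm = rm,
                 autoFeatures = autoFeatures, knots = as.integer(knots),
                 maxPasses = as.integer(maxPasses), tol = tol,
                 transform = match.arg(transform), clamp = clamp,
                 autoCutoffs = c(quadratic = 10, hinge = 15, threshold = 80,
                                 product = 80)),
            class = "maxentConfig")
}

enabledClasses <- function(config, m) {
  cls <- config$featureClasses
  if (isTRUE(config$autoFeatures)) {
    cut <- config$autoCutoffs
    for (cl in names(cut)) if (m < cut[[cl]]) cls <- setdiff(cls, cl)
  }
  cls
}

#' Expand variables into maxent features
#'
#' Variables are rescaled to [0, 1] by their background minimum and maximum.
#' Linear features are the scaled values; quadratic their squares; product
#' all pairwise products; threshold the step indicators value > knot; hinge
#' the forward ramp max(0, (value - knot) / (max - knot)) and its reverse
#' form. Knots sit at equally spaced quantiles of the background
#' distribution. A constant variable contributes only a zero feature (with a
#' warning) and is never given weight by the optimizer.
#'
#' @param pres,bg numeric matrices (rows = samples, columns = variables,
#'   matching colnames) of presence and background variable values.
#' @param config a \code{\link{maxentConfig}}.
#' @return list with \code{defs} (feature definition data.frame),
#'   \code{presF}/\code{bgF} (feature matrices), \code{scaling} (per-variable
#'   background min/max) and \code{classes} (the enabled feature classes).
#' @export
buildFeatures <- function(pres, bg, config = maxentConfig()) {
  if (is.null(colnames(bg)) || is.null(colnames(pres)))
    ncStop("variable matrices must have column names")
  vars <- colnames(bg)
  if (!identical(colnames(pres), vars))
    ncStop("presence and background variables disagree")
  if (nrow(bg) < 2) ncStop("at least 2 background samples required")
  mn <- apply(bg, 2, min)
  mx <- apply(bg, 2, max)
  const <- mx <= mn
  if (any(const))
    ncWarn(sprintf("constant variable(s): %s (zero feature only)",
                   paste(vars[const], collapse = ", ")))
  cls <- enabledClasses(config, nrow(pres))

  scaleVals <- function(x) {
    out <- sweep(sweep(x, 2, mn, "-"), 2, pmax(mx - mn, 1e-300), "/")
    out[, const] <- 0
    out
  }
  sPres <- scaleVals(pres)
  sBg <- scaleVals(bg)

  defs <- list()
  addDef <- function(class, var1, var2 = NA, knot = NA, reverse = FALSE) {
    defs[[length(defs) + 1]] <<- data.frame(
      class = class, var1 = var1, var2 = var2, knot = knot,
      reverse = reverse, stringsAsFactors = FALSE)
  }
  for (v in vars) addDef("linear", v)
  if ("quadratic" %in% cls) for (v in vars) addDef("quadratic", v)
  if ("product" %in% cls && length(vars) > 1) {
    for (i in seq_len(length(vars) - 1))
      for (j in seq(i + 1, length(vars)))
        addDef("product", vars[i], vars[j])
  }
  probs <- seq_len(config$knots) / (config$knots + 1)
  for (v in vars[!const]) {
    kts <- unique(stats::quantile(sBg[, v], probs, names = FALSE,
                                  type = 7))
    if ("threshold" %in% cls)
      for (k in kts[kts > 0 & kts < 1]) addDef("threshold", v, knot = k)
    if ("hinge" %in% cls) {
      for (k in kts[kts < 1]) addDef("hinge", v, knot = k)
      for (k in kts[kts > 0]) addDef("hinge", v, knot = k, reverse = TRUE)
    }
  }
  defs <- do.call(rbind, defs)
  list(defs = defs,
       presF = featureMatrix(defs, sPres),
       bgF = featureMatrix(defs, sBg),
       scaling = list(min = mn, max = mx, constant = const),
       classes = cls)
}

# Evaluate the feature basis on scaled ([0,1]) variable values.
featureMatrix <- function(defs, scaled) {
  out <- matrix(0, nrow(scaled), nrow(defs))
  for (k in seq_len(nrow(defs))) {
    d <- defs[k, ]
    x <- scaled[, d$var1]
    out[, k] <- switch(d$class,
      linear = x,
      quadratic = x^2,
      product = x * scaled[, d$var2],
      threshold = as.numeric(x > d$knot),
      hinge = if (d$reverse) pmax(0, (d$knot - x) / d$knot)
              else pmax(0, (x - d$knot) / (1 - d$knot)))
  }
  out
}

# Per-class base regularization constant rho, piecewise-linear in the number
# of presences m (published maxent defaults; hinge is the constant 0.5).
rhoClass <- function(class, m) {
  interp <- function(xs, ys)
    stats::approx(xs, ys, xout = min(max(m, xs[1]), xs[length(xs)]))$y
  switch(class,
    linear = ,
    quadratic = ,
    product = interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
    threshold = interp(c(0, 100), c(2, 1)),
    hinge = 0.5)
}

# L1 penalty per feature: lambda_k = RM * rho(class) * sd_k / sqrt(m), with
# sd over the background; exactly-constant features get an infinite penalty
# (never updated).
featureLambda <- function(defs, bgF, m, rm) {
  sdv <- apply(bgF, 2, stats::sd)
  rho <- vapply(defs$class, rhoClass, numeric(1), m = m)
  lambda <- rm * rho * pmax(sdv, 1e-3) / sqrt(m)
  lambda[sdv == 0] <- Inf
  lambda
}
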