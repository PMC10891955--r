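#' @include variable-selection.R
NULL

#' Rank-based AUC
#'
#' Area under the ROC curve as the probability that a randomly chosen
#' presence outscores a randomly chosen background point, with ties counted
#' one half (the Mann-Whitney estimator).
#'
#' @param presenceScores,backgroundScores numeric score vectors.
#' @return a number in [0, 1].
#' @export
#' @examples
#' auc(c(0.9, 0.8), c(0.1, 0.2))  # 1
auc <- function(presenceScores, backgroundScores) {
  np <- length(presenceScores)
  nb <- length(backgroundScores)
  if (!np || !nb) ncStop("both score lists must be non-empty")
  r <- rank(c(presenceScores, backgroundScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

# Seeded balanced partition of 1..n into k folds.
makeFolds <- function(n, k, seed) {
  if (k > n) ncStop("k exceeds the number of presences")
  withSeed(seed, sample(rep_len(seq_len(k), n)))
}

#' k-fold cross-validated AUC
#'
#' Presences are partitioned into k seeded, balanced folds; the background
#' is shared across folds. Per fold a model is trained on the remaining
#' presences and scored on the held-out presences against the background.
#' Out-of-fold presence scores and the per-fold background scores are pooled
#' and returned (they feed the sensitivity-plus-specificity threshold).
#'
#' @param presValues,bgValues variable matrices for presences/background.
#' @param config a \code{\link{maxentConfig}}.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold split.
#' @param bgWeights optional background weights passed to the fit.
#' @return an \code{evaluationReport}: list with \code{k}, \code{foldAUC},
#'   \code{meanAUC}, \code{sdAUC}, \code{models}, \code{pooled} (presence and
#'   background out-of-fold scores) and \code{folds}.
#' @export
crossValidate <- function(presValues, bgValues, config = maxentConfig(),
                          k = 10, seed, bgWeights = NULL) {
  if (missing(seed)) ncStop("seed is required")
  m <- nrow(presValues)
  folds <- makeFolds(m, k, seed)
  foldAUC <- numeric(k)
  models <- vector("list", k)
  presPooled <- numeric(m)
  bgPooled <- list()
  for (f in seq_len(k)) {
    hold <- folds == f
    fit <- maxentFit(presValues[!hold, , drop = FALSE], bgValues, config,
                     bgWeights = bgWeights, seed = seed)
    models[[f]] <- fit
    ps <- maxentPredict(fit, presValues[hold, , drop = FALSE])
    bs <- maxentPredict(fit, bgValues)
    foldAUC[f] <- auc(ps, bs)
    presPooled[hold] <- ps
    bgPooled[[f]] <- bs
  }
  structure(list(k = k, foldAUC = foldAUC, meanAUC = mean(foldAUC),
                 sdAUC = stats::sd(foldAUC), models = models,
                 pooled = list(presence = presPooled,
                               background = unlist(bgPooled)),
                 folds = folds),
            class = "evaluationReport")
}

#' @export
print.evaluationReport <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: mean AUC %.3f (sd %.3f)\n",
              x$k, x$meanAUC, x$sdAUC))
  invisible(x)
}

#' Jackknife test of variable importance
#'
#' For each variable, models are trained with only that variable and with
#' all variables but that one, per replicate (a seeded fold split of the
#' presences, matching the replicate structure of cross-validation), and
#' the regularized training gains are averaged over replicates, alongside
#' the full-model gain.
#'
#' @param presValues,bgValues variable matrices.
#' @param config a \code{\link{maxentConfig}}.
#' @param kReplicates number of replicates (default 10).
#' @param seed integer seed.
#' @return a \code{jackknifeResult}: list with per-variable
#'   \code{gainWithOnly}, \code{gainWithout} (means and sds) and
#'   \code{gainFull}.
#' @export
jackknife <- function(presValues, bgValues, config = maxentConfig(),
                      kReplicates = 10, seed) {
  if (missing(seed)) ncStop("seed is required")
  vars <- colnames(presValues)
  if (length(vars) < 2)
    ncWarn("single-variable jackknife is degenerate (without-model is null)")
  folds <- makeFolds(nrow(presValues), kReplicates, seed)
  gOnly <- gWithout <- matrix(NA_real_, kReplicates, length(vars),
                              dimnames = list(NULL, vars))
  gFull <- numeric(kReplicates)
  for (f in seq_len(kReplicates)) {
    tr <- presValues[folds != f, , drop = FALSE]
    gFull[f] <- regularizedGain(maxentFit(tr, bgValues, config))
    for (v in vars) {
      gOnly[f, v] <- regularizedGain(
        maxentFit(tr[, v, drop = FALSE], bgValues[, v, drop = FALSE],
                  config))
      if (length(vars) > 1)
        gWithout[f, v] <- regularizedGain(
          maxentFit(tr[, setdiff(vars, v), drop = FALSE],
                    bgValues[, setdiff(vars, v), drop = FALSE], config))
      else gWithout[f, v] <- 0
    }
  }
  structure(list(variables = vars,
                 gainWithOnly = colMeans(gOnly),
                 gainWithOnlySd = apply(gOnly, 2, stats::sd),
                 gainWithout = colMeans(gWithout),
                 gainWithoutSd = apply(gWithout, 2, stats::sd),
                 gainFull = mean(gFull), gainFullSd = stats::sd(gFull),
                 kReplicates = kReplicates),
            class = "jackknifeResult")
}

#' @export
print.jackknifeResult <- function(x, ...) {
  cat(sprintf("Jackknife gains over %d replicate(s), full-model gain %.3f:\n",
              x$kReplicates, x$gainFull))
  print(data.frame(variable = x$variables, with_only = x$gainWithOnly,
                   without = x$gainWithout, row.names = NULL))
  invisible(x)
}

#' Marginal response curve of one variable
#'
#' The variable is varied over the training background range while every
#' other variable is held at its mean over the presence records; the
#' predicted suitability is averaged over the supplied (replicate) models,
#' with its standard deviation.
#'
#' @param models a \linkS4class{MaxEntModel} or list of them (replicates).
#' @param variable variable name.
#' @param nPoints number of evaluation points (default 100).
#' @param transform output transform (default: each model's config).
#' @return a \code{responseCurve}: data.frame with \code{value},
#'   \code{meanP}, \code{sdP}.
#' @export
responseCurve <- function(models, variable, nPoints = 100,
                          transform = NULL) {
  if (is(models, "MaxEntModel")) models <- list(models)
  for (m in models)
    if (!variable %in% m@varNames)
      ncStop(sprintf("variable '%s' not in model", variable))
  m1 <- models[[1]]
  grid <- seq(m1@scaling$min[[variable]], m1@scaling$max[[variable]],
              length.out = nPoints)
  P <- vapply(models, function(m) {
    base <- matrix(m@presMeans[m@varNames], nPoints, length(m@varNames),
                   byrow = TRUE, dimnames = list(NULL, m@varNames))
    base[, variable] <- grid
    maxentPredict(m, base, transform = transform)
  }, numeric(nPoints))
  structure(data.frame(value = grid, meanP = rowMeans(P),
                       sdP = apply(P, 1, stats::sd)),
            variable = variable, class = c("responseCurve", "data.frame"))
}
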