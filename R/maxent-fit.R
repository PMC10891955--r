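#' @include maxent-features.R
NULL

softThreshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

#' Low-level penalized maxent optimizer
#'
#' Minimizes the penalized negative log-likelihood
#' \deqn{L(\beta) = -\frac{1}{m}\sum_{presences}\eta(x) +
#'   \log \sum_{background} w\, e^{\eta(z)} + \sum_k \lambda_k |\beta_k|}
#' with \eqn{\eta = \beta \cdot f}, by cyclic coordinate descent with a
#' soft-threshold Newton step per coordinate and backtracking so every
#' accepted update strictly decreases the objective. Background weights are
#' normalized to sum to 1, so the null model (\eqn{\beta = 0}) has objective
#' 0 and the regularized training gain is \eqn{G = -L(\hat\beta) \ge 0}.
#' Each accepted update's gain increase is credited to the updated feature's
#' source variable(s) (split equally for product features), which is the
#' ledger behind percent contribution.
#'
#' @param presF,bgF presence and background feature matrices (same columns).
#' @param lambda per-feature L1 penalty (Inf = frozen at zero).
#' @param bgWeights optional background weights (default uniform).
#' @param varOf optional list, per feature, of the source variable name(s)
#'   for gain attribution.
#' @param maxPasses,tol optimizer controls.
#' @return list with \code{beta}, \code{gain}, \code{gainTrace} (per pass),
#'   \code{logZ}, \code{entropy}, \code{contrib} (named accumulators),
#'   \code{converged}, \code{passes}.
#' @export
maxentCoreFit <- function(presF, bgF, lambda, bgWeights = NULL,
                          varOf = NULL, maxPasses = 2000, tol = 1e-6) {
  m <- nrow(presF)
  n <- nrow(bgF)
  if (m < 1) ncStop("at least 1 presence required")
  if (n < 2) ncStop("at least 2 background samples required")
  if (!all(is.finite(presF)) || !all(is.finite(bgF)))
    ncStop("features must be finite")
  nf <- ncol(bgF)
  if (length(lambda) != nf) ncStop("one lambda per feature required")
  p0 <- if (is.null(bgWeights)) rep(1 / n, n) else bgWeights / sum(bgWeights)
  presMean <- colMeans(presF)

  beta <- numeric(nf)
  etaB <- numeric(n)
  etaP <- numeric(m)
  objective <- function(etaB, etaP, beta) {
    mB <- max(etaB)
    -mean(etaP) + mB + log(sum(p0 * exp(etaB - mB))) +
      sum(lambda[is.finite(lambda)] * abs(beta[is.finite(lambda)]))
  }
  obj <- objective(etaB, etaP, beta)  # 0 by construction
  vars <- if (is.null(varOf)) as.list(paste0("f", seq_len(nf))) else varOf
  contrib <- stats::setNames(numeric(length(unique(unlist(vars)))),
                             unique(unlist(vars)))
  gainTrace <- numeric(0)
  updatable <- which(is.finite(lambda))
  converged <- FALSE
  pass <- 0L
  dense <- TRUE
  while (pass < maxPasses) {
    pass <- pass + 1L
    objStart <- obj
    # active-set strategy: after each dense pass, iterate over the nonzero
    # coefficients only until they stabilize, then check densely again
    active <- if (dense) updatable else updatable[beta[updatable] != 0]
    for (k in active) {
      fB <- bgF[, k]
      mB <- max(etaB)
      ew <- p0 * exp(etaB - mB)
      Z <- sum(ew)
      q <- ew / Z
      Eq <- sum(q * fB)
      h <- max(sum(q * fB * fB) - Eq^2, 1e-10)
      g <- Eq - presMean[k]
      bstar <- softThreshold(beta[k] - g / h, lambda[k] / h)
      d <- bstar - beta[k]
      if (abs(d) < 1e-12) next
      # backtrack toward the current value until the penalized objective
      # strictly decreases (quadratic model can overshoot)
      accepted <- FALSE
      for (bt in 1:25) {
        bNew <- beta[k] + d
        etaBNew <- etaB + d * fB
        etaPNew <- etaP + d * presF[, k]
        betaTry <- beta
        betaTry[k] <- bNew
        objNew <- objective(etaBNew, etaPNew, betaTry)
        if (objNew < obj - 1e-14) { accepted <- TRUE; break }
        d <- d / 2
        if (abs(d) < 1e-13) break
      }
      if (accepted) {
        inc <- obj - objNew
        for (v in vars[[k]]) contrib[v] <- contrib[v] + inc / length(vars[[k]])
        beta[k] <- bNew
        etaB <- etaBNew
        etaP <- etaPNew
        obj <- objNew
      }
    }
    gainTrace <- c(gainTrace, -obj)
    if (objStart - obj < tol) {
      if (dense) { converged <- TRUE; break }
      dense <- TRUE
    } else dense <- FALSE
  }
  mB <- max(etaB)
  logZ <- mB + log(sum(p0 * exp(etaB - mB)))
  q <- p0 * exp(etaB - logZ)
  entropy <- -sum(ifelse(q > 0, q * log(q), 0))
  list(beta = beta, gain = -obj, gainTrace = gainTrace, logZ = logZ,
       entropy = entropy, contrib = contrib, converged = converged,
       passes = pass, nBackground = n)
}

#' Fit a maximum-entropy presence-background model
#'
#' Expands the variables into the configured feature classes
#' (\code{\link{buildFeatures}}), derives the per-feature L1 penalties
#' \eqn{\lambda_k = RM\,\rho(class_k)\,sd_k/\sqrt{m}} from the published
#' per-class defaults, and runs \code{\link{maxentCoreFit}}.
#'
#' @param pres,bg numeric matrices of presence and background variable
#'   values (matching colnames).
#' @param config a \code{\link{maxentConfig}}.
#' @param bgWeights optional background weights (e.g. from a sampling-bias
#'   surface).
#' @param seed recorded in the model metadata (the optimizer itself is
#'   deterministic).
#' @return a \linkS4class{MaxEntModel}.
#' @export
#' @examples
#' bg <- cbind(x = runif(200))
#' pres <- cbind(x = runif(40, 0.5, 1))
#' m <- maxentFit(pres, bg, maxentConfig(knots = 5))
#' regularizedGain(m)
maxentFit <- function(pres, bg, config = maxentConfig(), bgWeights = NULL,
                      seed = NA_real_) {
  fb <- buildFeatures(pres, bg, config)
  lambda <- featureLambda(fb$defs, fb$bgF, nrow(pres), config$rm)
  varOf <- lapply(seq_len(nrow(fb$defs)), function(k) {
    d <- fb$defs[k, ]
    if (!is.na(d$var2)) c(d$var1, d$var2) else d$var1
  })
  fit <- maxentCoreFit(fb$presF, fb$bgF, lambda, bgWeights = bgWeights,
                       varOf = varOf, maxPasses = config$maxPasses,
                       tol = config$tol)
  if (!fit$converged)
    ncWarn(sprintf("optimizer hit the pass limit (%d) before converging",
                   config$maxPasses))
  contrib <- stats::setNames(numeric(ncol(bg)), colnames(bg))
  contrib[names(fit$contrib)] <- fit$contrib
  defs <- fb$defs
  defs$lambda <- lambda
  new("MaxEntModel", features = defs, beta = fit$beta,
      varNames = colnames(bg), scaling = fb$scaling,
      presMeans = colMeans(pres), logZ = fit$logZ, entropy = fit$entropy,
      gain = max(fit$gain, 0), gainTrace = fit$gainTrace, contrib = contrib,
      config = unclass(config), converged = fit$converged,
      passes = fit$passes, nBackground = fit$nBackground,
      seed = as.numeric(seed))
}

#' Regularized training gain of a fitted model
#'
#' The penalized log-likelihood improvement of the fit over the uniform
#' (null) distribution on the training background; exactly 0 for the null
#' model.
#'
#' @param model a \linkS4class{MaxEntModel}.
#' @return a single nonnegative number.
#' @export
regularizedGain <- function(model) model@gain

#' Percent contribution of each variable
#'
#' Normalizes the per-variable accumulated gain increments recorded during
#' training (negative accumulators clipped to zero) to sum to 100.
#'
#' @param model a \linkS4class{MaxEntModel}.
#' @return named numeric vector of percentages (all zero, with a warning, if
#'   no feature was ever updated).
#' @export
percentContribution <- function(model) {
  acc <- pmax(model@contrib, 0)
  tot <- sum(acc)
  if (tot <= 0) {
    ncWarn("no gain was accumulated; contributions are all zero")
    return(acc)
  }
  100 * acc / tot
}
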