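#' @include maxent-predict.R
NULL

#' Pearson correlations at presence records
#'
#' Standard Pearson coefficients between all pairs of environmental
#' variables, computed over the values extracted at the presence records
#' only (not over all grid cells). A zero-variance variable gets 0 in its
#' off-diagonal entries, with a warning.
#'
#' @param grid an \linkS4class{EnvGrid}.
#' @param occ located \linkS4class{Occurrences}; records off-grid or on
#'   nodata cells are ignored.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearsonAtPresences <- function(grid, occ) {
  if (is.null(occ@records$row)) occ <- locateCells(occ, grid@geometry)
  vals <- extractAtRecords(grid, occ)
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  if (nrow(vals) < 3) ncStop("need at least 3 presence records on valid cells")
  v <- apply(vals, 2, stats::var)
  r <- suppressWarnings(stats::cor(vals))
  if (any(v == 0)) {
    ncWarn(sprintf("zero-variance variable(s) at presences: %s",
                   paste(colnames(vals)[v == 0], collapse = ", ")))
    r[v == 0, ] <- 0
    r[, v == 0] <- 0
  }
  diag(r) <- 1
  r
}

#' Two-stage correlation / contribution variable selection
#'
#' Stage A (all-pairs correlation rule): a variable is dropped if and only
#' if ANY variable with strictly higher percent contribution has
#' \eqn{|r| >} \code{rThreshold} with it; the rule is evaluated
#' simultaneously over all pairs, so the result is independent of variable
#' order. Stage B: surviving variables whose contribution is at most
#' \code{minContribution} are dropped. Both comparisons are strict, and the
#' correlation rule uses the absolute value of r.
#'
#' An exact contribution tie inside a violating pair is an error whenever it
#' would decide a variable's fate (neither member has a strictly higher
#' correlated partner): silently breaking such a tie would be invisible
#' nondeterminism, so an explicit perturbation of the inputs is demanded
#' instead. A tie between two variables that are each dropped anyway by a
#' strictly higher partner is immaterial and tolerated.
#'
#' @param corr symmetric correlation matrix with variable names.
#' @param contributions named numeric vector of percent contributions
#'   covering every matrix variable.
#' @param rThreshold correlation threshold (default 0.7).
#' @param minContribution retention threshold in percent (default 1.0).
#' @return a \code{selectionReport}: list with \code{kept} (ordered by
#'   decreasing contribution), \code{dropped} (data.frame with reason,
#'   partner, r, contribution) and the thresholds used.
#' @export
#' @examples
#' fx <- loadPaperFixtures()
#' selectVariables(fx$correlation, fx$contributions)$kept
selectVariables <- function(corr, contributions, rThreshold = 0.7,
                            minContribution = 1.0) {
  vars <- rownames(corr)
  if (is.null(vars) || !identical(vars, colnames(corr)))
    ncStop("corr must have matching row/column variable names")
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)))
    ncStop("corr must be symmetric")
  missing <- setdiff(vars, names(contributions))
  if (length(missing))
    ncStop(sprintf("missing contribution for: %s",
                   paste(missing, collapse = ", ")))
  contrib <- contributions[vars]

  dropped <- list()
  stageA <- character()
  for (v in vars) {
    over <- vars[abs(corr[v, ]) > rThreshold & vars != v]
    rivals <- over[contrib[over] > contrib[v]]
    ties <- over[contrib[over] == contrib[v]]
    # a tie is only ambiguous when it decides the variable's fate: with a
    # strictly-higher violating partner the variable is dropped regardless
    if (length(ties) && !length(rivals))
      ncStop(sprintf(paste("contribution tie between '%s' and '%s' inside a",
                           "correlated pair; supply an explicit tie-break"),
                     v, ties[1]))
    if (length(rivals)) {
      best <- rivals[which.max(abs(corr[v, rivals]))]
      stageA <- c(stageA, v)
      dropped[[v]] <- data.frame(
        variable = v, reason = "correlated", partner = best,
        r = corr[v, best], contribution = unname(contrib[v]),
        stringsAsFactors = FALSE)
    }
  }
  survivors <- setdiff(vars, stageA)
  stageB <- survivors[contrib[survivors] <= minContribution]
  for (v in stageB)
    dropped[[v]] <- data.frame(
      variable = v, reason = "low_contribution", partner = NA_character_,
      r = NA_real_, contribution = unname(contrib[v]),
      stringsAsFactors = FALSE)
  kept <- setdiff(survivors, stageB)
  kept <- kept[order(-contrib[kept])]
  structure(list(
    kept = kept,
    keptContributions = stats::setNames(unname(contrib[kept]), kept),
    dropped = if (length(dropped)) do.call(rbind, unname(dropped))
              else data.frame(variable = character(), reason = character(),
                              partner = character(), r = numeric(),
                              contribution = numeric()),
    rThreshold = rThreshold, minContribution = minContribution),
    class = "selectionReport")
}

#' @export
print.selectionReport <- function(x, ...) {
  cat(sprintf("Variable selection (|r| > %g, contribution > %g%%):\n",
              x$rThreshold, x$minContribution))
  cat("  kept:", paste(sprintf("%s (%.1f%%)", x$kept,
                               x$keptContributions), collapse = ", "), "\n")
  cat(sprintf("  dropped: %d (%d correlated, %d low-contribution)\n",
              nrow(x$dropped), sum(x$dropped$reason == "correlated"),
              sum(x$dropped$reason == "low_contribution")))
  invisible(x)
}

#' Serialize a selection report to JSON
#'
#' @param report a \code{selectionReport}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
selectionReportToJSON <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
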