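#' @include synthetic-world.R
NULL

# md5 checksums of the packaged worked-example fixtures; guards silent edits.
.fixtureChecksums <- c(
  "table1_pearson.csv" = NA_character_,     # filled at load via integrity csv
  "table2_contributions.csv" = NA_character_,
  "table3_contributions.csv" = NA_character_)

#' Load the packaged worked-example fixtures
#'
#' Returns the 20-variable pairwise Pearson correlation matrix of the
#' bioclimatic predictors at the presence records, the percent-contribution
#' table of the initial 20-variable model, and the contribution table of the
#' final three-variable model, as shipped with the package. These drive the
#' in-package worked example of the two-stage variable-selection rule.
#'
#' Note: the variable set follows the source convention of naming elevation
#' "bio20" alongside the 19 standard bioclimatic variables.
#'
#' @return list with \code{variables} (character), \code{correlation}
#'   (20 x 20 matrix), \code{contributions} (named numeric, percent) and
#'   \code{finalContributions} (named numeric, percent).
#' @export
#' @examples
#' fx <- loadPaperFixtures()
#' fx$correlation["bio11", "bio3"]
loadPaperFixtures <- function() {
  dir <- system.file("extdata", package = "nichecast")
  paths <- file.path(dir, names(.fixtureChecksums))
  if (!all(file.exists(paths)))
    ncStop("packaged fixture files are missing",
           class = "nichecast_integrity_error")
  sums <- file.path(dir, "fixture_checksums.csv")
  if (file.exists(sums)) {
    expect <- utils::read.csv(sums, stringsAsFactors = FALSE)
    got <- as.character(tools::md5sum(paths))
    bad <- expect$md5[match(basename(paths), expect$file)] != got
    if (any(bad, na.rm = TRUE))
      ncStop(sprintf("fixture checksum mismatch: %s",
                     paste(basename(paths)[which(bad)], collapse = ", ")),
             class = "nichecast_integrity_error")
  }
  corrDf <- utils::read.csv(paths[1], check.names = FALSE,
                            stringsAsFactors = FALSE)
  vars <- corrDf$variable
  corr <- as.matrix(corrDf[, -1])
  rownames(corr) <- vars
  storage.mode(corr) <- "double"
  if (!isTRUE(all.equal(corr, t(corr))) || any(diag(corr) != 1) ||
      any(abs(corr) > 1))
    ncStop("correlation fixture failed validation",
           class = "nichecast_integrity_error")
  contribDf <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  finalDf <- utils::read.csv(paths[3], stringsAsFactors = FALSE)
  if (any(contribDf$contribution < 0))
    ncStop("contributions must be nonnegative",
           class = "nichecast_integrity_error")
  list(variables = vars,
       correlation = corr,
       contributions = stats::setNames(contribDf$contribution,
                                       contribDf$variable),
       finalContributions = stats::setNames(finalDf$contribution,
                                            finalDf$variable))
}
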