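#' @include suitability.R
NULL

pipelineDefaults <- function() {
  list(
    outDir = NULL,
    seed = NULL,
    world = list(nrow = 100, ncol = 100, smoothness = 4),
    presences = list(n = 300, samplingBias = FALSE),
    prep = list(backgroundN = 10000, biasBandwidth = NULL,
                biasedBackground = TRUE),
    maxent = list(rm = 1, knots = 20, transform = "cloglog", clamp = TRUE,
                  maxPasses = 2000, tol = 1e-6),
    selection = list(rThreshold = 0.7, minContribution = 1.0),
    evaluation = list(k = 10, jackknifeReplicates = 10,
                      responsePoints = 100),
    scenarios = "default")
}

mergeStrict <- function(defaults, user, path = "config") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    ncStop(sprintf("unknown %s key(s): %s", path,
                   paste(unknown, collapse = ", ")),
           class = "nichecast_config_error")
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]]))
      defaults[[k]] <- mergeStrict(defaults[[k]], user[[k]],
                                   paste(path, k, sep = "$"))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Assemble and validate a pipeline configuration
#'
#' Unknown keys are errors (a silent typo would corrupt scientific
#' settings). The defaults describe the standard synthetic study world; see
#' the package vignette for every knob.
#'
#' @param outDir output directory for all artifacts.
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it and its stage label.
#' @param ... overrides of the default blocks (\code{world},
#'   \code{presences}, \code{prep}, \code{maxent}, \code{selection},
#'   \code{evaluation}, \code{scenarios}).
#' @return a validated config (class \code{pipelineConfig}).
#' @export
pipelineConfig <- function(outDir, seed, ...) {
  cfg <- mergeStrict(pipelineDefaults(), list(...))
  cfg$outDir <- outDir
  cfg$seed <- seed
  if (is.null(cfg$outDir) || is.null(cfg$seed))
    ncStop("outDir and seed are required",
           class = "nichecast_config_error")
  thr <- cfg$selection
  if (thr$rThreshold < 0 || thr$rThreshold > 1)
    ncStop("selection$rThreshold must lie in [0, 1]",
           class = "nichecast_config_error")
  if (cfg$maxent$rm <= 0)
    ncStop("maxent$rm must be positive", class = "nichecast_config_error")
  structure(cfg, class = "pipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror
#'   \code{\link{pipelineConfig}} arguments.
#' @return a validated config.
#' @export
loadPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  outDir <- y$outDir
  seed <- y$seed
  y$outDir <- NULL
  y$seed <- NULL
  do.call(pipelineConfig, c(list(outDir = outDir, seed = seed), y))
}

defaultScenarios <- function(bandRoles) {
  temps <- names(bandRoles)[bandRoles == "temperature"]
  precs <- names(bandRoles)[bandRoles == "precipitation"]
  mk <- function(label, dT, fP)
    scenarioSpec(label, add = stats::setNames(rep(dT, length(temps)), temps),
                 mult = stats::setNames(rep(fP, length(precs)), precs))
  list(mk("low-emission-2030", 0.8, 1.04), mk("low-emission-2050", 1.2, 1.06),
       mk("high-emission-2030", 1.4, 1.07), mk("high-emission-2050", 3.0, 1.12))
}

writeJsonArtifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic-world simulation (or raster/occurrence
#' loading), occurrence cleaning (deduplication, nodata-mask filtering,
#' one-per-cell thinning), kernel bias surface and background sampling,
#' the initial all-variable maxent model and its percent contributions,
#' Pearson correlations at the presences, two-stage variable selection, the
#' final model on the kept variables, k-fold cross-validated AUC, jackknife
#' importance, response curves, the sensitivity-plus-specificity threshold
#' on pooled out-of-fold predictions, classification of the current
#' suitability map, projection and classification of every scenario, and
#' class-change summaries against the current map. Every artifact is
#' written under \code{config$outDir}; identical config and seed give
#' byte-identical JSON/CSV artifacts.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return a run manifest (list): config echo, per-stage status and wall
#'   time, and per-artifact md5 hashes.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "pipelineConfig"))
    ncStop("config must come from pipelineConfig()",
           class = "nichecast_config_error")
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config),
                   version = as.character(utils::packageVersion("nichecast")),
                   stages = list(), artifacts = list(), warnings = list())
  state <- new.env(parent = emptyenv())
  addArtifact <- function(path) {
    manifest$artifacts[[basename(path)]] <<-
      unname(as.character(tools::md5sum(path)))
  }
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(withCallingHandlers(fun(), warning = function(w) {
      manifest$warnings[[length(manifest$warnings) + 1]] <<-
        list(stage = name, message = conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) e)
    wall <- proc.time()[["elapsed"]] - t0
    ok <- !inherits(res, "error")
    manifest$stages[[length(manifest$stages) + 1]] <<-
      list(name = name, status = if (ok) "ok" else "failed",
           wallTime = round(wall, 3),
           error = if (ok) NULL else conditionMessage(res))
    if (!ok) {
      writeJsonArtifact(manifest, file.path(outDir, "manifest.json"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(res)), call. = FALSE)
    }
    res
  }
  seedOf <- function(label) deriveSeed(config$seed, label)

  stage("simulate", function() {
    world <- makeDefaultWorld(seedOf("world"), nrow = config$world$nrow,
                              ncol = config$world$ncol,
                              smoothness = config$world$smoothness)
    state$world <- world
    bias <- NULL
    if (isTRUE(config$presences$samplingBias)) {
      # an east-west survey-effort gradient as the planted sampling bias
      g <- world$grid@geometry
      w <- matrix(rep(seq(0.2, 1, length.out = g@ncol), each = g@nrow),
                  g@nrow, g@ncol)
      w[world$grid@mask] <- 0
      bias <- new("BiasSurface", geometry = g, weights = w,
                  normalization = "max1")
    }
    state$occ <- sampleOccurrences(world$suitability, config$presences$n,
                                   biasSurface = bias,
                                   seed = seedOf("presences"))
    invisible(NULL)
  })

  stage("prep", function() {
    grid <- state$world$grid
    occ <- locateCells(state$occ, grid@geometry)
    d <- deduplicate(occ)
    f <- maskFilter(d$occurrences, grid)
    t <- thinOnePerCell(f$occurrences, grid@geometry, seed = seedOf("thin"))
    state$occ <- t$occurrences
    state$bias <- kernelBiasSurface(t$occurrences, grid@geometry,
                                    bandwidth = config$prep$biasBandwidth,
                                    mask = grid@mask)
    state$bg <- sampleBackground(
      grid, n = config$prep$backgroundN,
      bias = if (isTRUE(config$prep$biasedBackground)) state$bias,
      seed = seedOf("background"))
    rep <- list(deduplicate = unclass(d$report),
                maskFilter = unclass(f$report), thin = unclass(t$report))
    addArtifact(writeJsonArtifact(rep, file.path(outDir,
                                                 "prep_report.json")))
    df <- state$occ@records
    p <- file.path(outDir, "occurrences.csv")
    utils::write.csv(df, p, row.names = FALSE)
    addArtifact(p)
    invisible(NULL)
  })

  mkConfig <- function() do.call(maxentConfig, config$maxent)

  stage("initial_fit", function() {
    grid <- state$world$grid
    state$presVals <- extractAtRecords(grid, state$occ)
    bgIdx <- cbind(state$bg$row, state$bg$col)
    state$bgVals <- vapply(seq_along(grid@bandNames),
                           function(b) grid@values[, , b][bgIdx],
                           numeric(nrow(state$bg)))
    colnames(state$bgVals) <- grid@bandNames
    state$initialModel <- maxentFit(state$presVals, state$bgVals,
                                    mkConfig(), seed = seedOf("initial"))
    invisible(NULL)
  })

  stage("contributions", function() {
    pc <- percentContribution(state$initialModel)
    state$contrib <- pc
    p <- file.path(outDir, "initial_contributions.csv")
    utils::write.csv(data.frame(variable = names(pc),
                                contribution = unname(pc)),
                     p, row.names = FALSE)
    addArtifact(p)
    invisible(NULL)
  })

  stage("pearson", function() {
    r <- pearsonAtPresences(state$world$grid, state$occ)
    state$pearson <- r
    p <- file.path(outDir, "pearson.csv")
    utils::write.csv(data.frame(variable = rownames(r), r,
                                check.names = FALSE), p, row.names = FALSE)
    addArtifact(p)
    invisible(NULL)
  })

  stage("select", function() {
    sel <- selectVariables(state$pearson, state$contrib,
                           rThreshold = config$selection$rThreshold,
                           minContribution = config$selection$minContribution)
    state$selection <- sel
    addArtifact(selectionReportToJSON(sel, file.path(outDir,
                                                     "selection.json")))
    invisible(NULL)
  })

  stage("final_fit", function() {
    kept <- state$selection$kept
    if (!length(kept)) stop("no variables survived selection")
    state$finalModel <- maxentFit(state$presVals[, kept, drop = FALSE],
                                  state$bgVals[, kept, drop = FALSE],
                                  mkConfig(), seed = seedOf("final"))
    addArtifact(modelToJSON(state$finalModel,
                            file.path(outDir, "final_model.json")))
    invisible(NULL)
  })

  stage("cross_validate", function() {
    kept <- state$selection$kept
    ev <- crossValidate(state$presVals[, kept, drop = FALSE],
                        state$bgVals[, kept, drop = FALSE], mkConfig(),
                        k = config$evaluation$k, seed = seedOf("cv"))
    state$evaluation <- ev
    addArtifact(writeJsonArtifact(
      list(k = ev$k, foldAUC = ev$foldAUC, meanAUC = ev$meanAUC,
           sdAUC = ev$sdAUC),
      file.path(outDir, "evaluation.json")))
    invisible(NULL)
  })

  stage("jackknife", function() {
    kept <- state$selection$kept
    jk <- jackknife(state$presVals[, kept, drop = FALSE],
                    state$bgVals[, kept, drop = FALSE], mkConfig(),
                    kReplicates = config$evaluation$jackknifeReplicates,
                    seed = seedOf("jackknife"))
    state$jackknife <- jk
    addArtifact(writeJsonArtifact(
      unclass(jk)[c("variables", "gainWithOnly", "gainWithout",
                    "gainFull")],
      file.path(outDir, "jackknife.json")))
    invisible(NULL)
  })

  stage("response_curves", function() {
    for (v in state$selection$kept) {
      rc <- responseCurve(state$evaluation$models, v,
                          nPoints = config$evaluation$responsePoints)
      p <- file.path(outDir, sprintf("response_%s.csv", v))
      utils::write.csv(as.data.frame(rc), p, row.names = FALSE)
      addArtifact(p)
    }
    invisible(NULL)
  })

  stage("mtsps", function() {
    thr <- mtspsThreshold(state$evaluation$pooled$presence,
                          state$evaluation$pooled$background)
    state$threshold <- thr
    addArtifact(writeJsonArtifact(unclass(thr),
                                  file.path(outDir, "threshold.json")))
    invisible(NULL)
  })

  stage("classify_current", function() {
    suit <- maxentPredict(state$finalModel, state$world$grid,
                          label = "current")
    state$currentMap <- suppressMessages(classify(suit,
                                                  state$threshold$mtsps))
    p <- file.path(outDir, "classified_current.asc")
    writeClassifiedMap(state$currentMap, p)
    addArtifact(p)
    addArtifact(paste0(p, ".legend.json"))
    invisible(NULL)
  })

  stage("project_scenarios", function() {
    scens <- config$scenarios
    if (identical(scens, "default"))
      scens <- defaultScenarios(state$world$bandRoles)
    else
      scens <- lapply(scens, function(s)
        scenarioSpec(s$label, add = unlist(s$add), mult = unlist(s$mult)))
    state$scenarioMaps <- list()
    for (s in scens) {
      pg <- applyScenario(state$world$grid, s)
      suit <- project(state$finalModel, pg, label = s$label)
      cm <- suppressMessages(classify(suit, state$threshold$mtsps))
      state$scenarioMaps[[s$label]] <- cm
      p <- file.path(outDir, sprintf("classified_%s.asc", s$label))
      writeClassifiedMap(cm, p)
      addArtifact(p)
      addArtifact(paste0(p, ".legend.json"))
    }
    invisible(NULL)
  })

  stage("change_summary", function() {
    for (label in names(state$scenarioMaps)) {
      cs <- changeSummary(state$currentMap, state$scenarioMaps[[label]])
      p <- file.path(outDir, sprintf("change_%s.csv", label))
      utils::write.csv(data.frame(from = rownames(cs$transitions),
                                  cs$transitions, check.names = FALSE),
                       p, row.names = FALSE)
      addArtifact(p)
    }
    invisible(NULL)
  })

  manifestPath <- file.path(outDir, "manifest.json")
  writeJsonArtifact(manifest, manifestPath)
  invisible(manifest)
}

#' Worked-example selection on the packaged fixtures
#'
#' Runs the two-stage variable selection on the packaged correlation and
#' contribution fixtures and checks that the kept set matches the packaged
#' final-model table.
#'
#' @return the \code{selectionReport}, with the final-model contribution
#'   table attached as attribute \code{"finalContributions"}.
#' @export
#' @examples
#' fixturePipeline()$kept
fixturePipeline <- function() {
  fx <- loadPaperFixtures()
  sel <- selectVariables(fx$correlation, fx$contributions)
  expected <- names(fx$finalContributions)
  if (!setequal(sel$kept, expected)) {
    print(sel$dropped)
    ncStop(sprintf(
      "fixture selection mismatch: kept {%s}, expected {%s}; drop ledger above",
      paste(sel$kept, collapse = ", "), paste(expected, collapse = ", ")),
      class = "nichecast_integrity_error")
  }
  attr(sel, "finalContributions") <- fx$finalContributions
  sel
}
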