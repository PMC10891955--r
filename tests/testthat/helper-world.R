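# Shared fixtures built in code: small geometries, a desk-scale synthetic
# world, and cached evaluations of the default study world (several
# acceptance checks share the same 10-seed cross-validation runs).

tinyGeom <- function(nrow = 10, ncol = 10, cellSize = 1)
  gridGeometry(nrow, ncol, xOrigin = 0, yOrigin = nrow * cellSize,
               cellSize = cellSize)

# band values at sampled background cells
bgValuesAt <- function(grid, bg) {
  out <- vapply(seq_along(bandNames(grid)),
                function(b) grid@values[, , b][cbind(bg$row, bg$col)],
                numeric(nrow(bg)))
  colnames(out) <- bandNames(grid)
  out
}

presValuesOf <- function(grid, occ) {
  occ <- locateCells(occ, geometry(grid))
  nichecast:::extractAtRecords(grid, occ)
}

# small world + presence/background matrices for engine-level tests
smallDataset <- function(seed, n = 120, bgN = 600, nrow = 40, ncol = 40) {
  w <- makeDefaultWorld(seed = seed, nrow = nrow, ncol = ncol)
  occ <- locateCells(sampleOccurrences(w$suitability, n, seed = seed + 1),
                     geometry(w$grid))
  occ <- thinOnePerCell(occ, geometry(w$grid), seed = seed + 2)$occurrences
  bg <- sampleBackground(w$grid, bgN, seed = seed + 3)
  list(world = w, occ = occ,
       pres = presValuesOf(w$grid, occ), bgv = bgValuesAt(w$grid, bg))
}

# Default-world 10-fold cross-validation at the standard testbed scale,
# cached: several checks (discrimination, threshold, parameter recovery)
# read the same runs.
.worldEvalCache <- new.env(parent = emptyenv())
defaultWorldEval <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.worldEvalCache[[key]])) return(.worldEvalCache[[key]])
  w <- makeDefaultWorld(seed = deriveSeed(seed, "world"))
  g <- geometry(w$grid)
  occ <- locateCells(
    sampleOccurrences(w$suitability, 300, seed = deriveSeed(seed, "pres")),
    g)
  occ <- thinOnePerCell(occ, g, seed = deriveSeed(seed, "thin"))$occurrences
  bg <- sampleBackground(w$grid, 2000, seed = deriveSeed(seed, "bg"))
  pres <- presValuesOf(w$grid, occ)
  bgv <- bgValuesAt(w$grid, bg)
  kept <- c("temp_cold", "prec_wet", "prec_dry")
  ev <- crossValidate(pres[, kept], bgv[, kept], maxentConfig(knots = 10),
                      k = 10, seed = deriveSeed(seed, "cv"))
  res <- list(world = w, pres = pres, bgv = bgv, kept = kept, ev = ev)
  .worldEvalCache[[key]] <- res
  res
}

# Independent penalized-objective evaluator used by the optimizer oracles:
# deliberately a direct transcription of the objective, sharing no code with
# the coordinate-descent implementation.
bruteObjective <- function(beta, presF, bgF, lambda) {
  etaP <- presF %*% beta
  etaB <- bgF %*% beta
  -mean(etaP) + log(mean(exp(etaB))) + sum(lambda * abs(beta))
}

# exhaustive candidate scan for the sensitivity+specificity threshold
bruteMTSPS <- function(p, b) {
  cand <- sort(unique(c(p, b)))
  tot <- vapply(cand, function(t) mean(p >= t) + mean(b < t), numeric(1))
  cand[which(tot == max(tot))[1]]
}
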