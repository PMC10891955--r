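test_that("the rank-based AUC equals the exhaustive pair oracle", {
  expect_equal(auc(c(1, 1, 1), c(0, 0)), 1)
  expect_error(auc(numeric(), 1), "non-empty")

  pairOracle <- function(p, b) {
    s <- outer(p, b, function(x, y) (x > y) + 0.5 * (x == y))
    mean(s)
  }
  expect_equal(auc(c(0.9, 0.7, 0.5, 0.4, 0.3, 0.2),
                   c(0.8, 0.6, 0.5, 0.3, 0.1, 0.05)),
               pairOracle(c(0.9, 0.7, 0.5, 0.4, 0.3, 0.2),
                          c(0.8, 0.6, 0.5, 0.3, 0.1, 0.05)))
  set.seed(601)
  for (i in 1:25) {
    np <- sample(1:20, 1); nb <- sample(1:20, 1)
    p <- sample(seq(0, 1, 0.1), np, replace = TRUE)  # plenty of ties
    b <- sample(seq(0, 1, 0.1), nb, replace = TRUE)
    expect_identical(auc(p, b), pairOracle(p, b))
  }
})

test_that("scores from one distribution give a chance-level AUC", {
  set.seed(602)
  expect_lt(abs(auc(rnorm(10000), rnorm(10000)) - 0.5), 0.02)
})

test_that("cross-validation partitions presences and is seed-stable", {
  d <- smallDataset(603)
  kept <- c("temp_cold", "prec_dry")
  cfg <- maxentConfig(knots = 6)
  ev <- crossValidate(d$pres[, kept], d$bgv[, kept], cfg, k = 5, seed = 604)
  expect_equal(sort(unique(ev$folds)), 1:5)
  expect_equal(length(ev$folds), nrow(d$pres))
  expect_equal(ev$meanAUC, mean(ev$foldAUC), tolerance = 1e-12)
  expect_equal(ev$sdAUC, sd(ev$foldAUC), tolerance = 1e-12)
  expect_true(all(ev$foldAUC >= 0 & ev$foldAUC <= 1))
  ev2 <- crossValidate(d$pres[, kept], d$bgv[, kept], cfg, k = 5, seed = 604)
  expect_identical(ev$foldAUC, ev2$foldAUC)
  expect_identical(ev$folds, ev2$folds)
  expect_error(crossValidate(d$pres[, kept], d$bgv[, kept], cfg,
                             k = nrow(d$pres) + 1, seed = 1), "exceeds")
})

test_that("suitability-independent presences score near chance", {
  d <- smallDataset(605)
  kept <- c("temp_cold", "prec_wet", "prec_dry")
  # presences re-drawn uniformly over valid cells, ignoring suitability
  g <- geometry(d$world$grid)
  uni <- new("SuitabilityMap", geometry = g,
             values = matrix(1, g@nrow, g@ncol) +
               0 * suitabilityValues(d$world$suitability),
             mask = nodataMask(d$world$grid), transform = "true",
             label = "uniform")
  occ <- locateCells(sampleOccurrences(uni, 120, seed = 606), g)
  pres <- nichecast:::extractAtRecords(d$world$grid, occ)
  ev <- crossValidate(pres, d$bgv, maxentConfig(knots = 6), k = 5,
                      seed = 607)
  expect_lt(abs(ev$meanAUC - 0.5), 0.05)
})

test_that("jackknife gains behave like nested models", {
  d <- smallDataset(608)
  kept <- c("temp_cold", "prec_wet", "prec_dry")
  jk <- jackknife(d$pres[, kept], d$bgv[, kept], maxentConfig(knots = 6),
                  kReplicates = 3, seed = 609)
  expect_true(all(jk$gainWithOnly >= 0))
  expect_true(all(jk$gainWithout <= jk$gainFull + 1e-6))
  expect_true(all(jk$gainWithOnly <= jk$gainFull + 1e-6))

  # a pure-noise variable carries essentially no gain on its own
  set.seed(610)
  noisy <- cbind(d$pres[, kept], noise = runif(nrow(d$pres)))
  bgN <- cbind(d$bgv[, kept], noise = runif(nrow(d$bgv)))
  jkN <- jackknife(noisy, bgN, maxentConfig(knots = 6), kReplicates = 2,
                   seed = 611)
  expect_lt(jkN$gainWithOnly[["noise"]], 0.05)

  # omitting one of two near-duplicate informative variables barely matters
  dup <- cbind(d$pres[, kept],
               temp_copy = d$pres[, "temp_cold"] + rnorm(nrow(d$pres), 0, 0.05))
  bgD <- cbind(d$bgv[, kept],
               temp_copy = d$bgv[, "temp_cold"] + rnorm(nrow(d$bgv), 0, 0.05))
  jkD <- jackknife(dup, bgD, maxentConfig(knots = 6), kReplicates = 2,
                   seed = 612)
  expect_lt(abs(jkD$gainWithout[["temp_copy"]] - jkD$gainFull),
            0.05 * jkD$gainFull + 1e-9)
})

test_that("response curves expose the fitted marginal structure", {
  d <- smallDataset(613)
  kept <- c("temp_cold", "prec_dry")
  null <- suppressWarnings(
    maxentFit(d$bgv[, kept], d$bgv[, kept],
              maxentConfig(knots = 3, autoFeatures = FALSE)))
  rc <- responseCurve(null, "temp_cold", nPoints = 50)
  expect_lt(diff(range(rc$meanP)), 1e-10)
  expect_true(all(diff(rc$value) > 0))

  # single-variable model with a negative quadratic coefficient peaks at
  # the analytic vertex of the parabola
  m <- maxentFit(d$pres[, "temp_cold", drop = FALSE],
                 d$bgv[, "temp_cold", drop = FALSE],
                 maxentConfig(featureClasses = c("linear", "quadratic"),
                              autoFeatures = FALSE))
  bL <- m@beta[m@features$class == "linear"]
  bQ <- m@beta[m@features$class == "quadratic"]
  if (bQ < 0) {
    vertexScaled <- min(max(-bL / (2 * bQ), 0), 1)
    vertex <- m@scaling$min[["temp_cold"]] +
      vertexScaled * (m@scaling$max[["temp_cold"]] -
                        m@scaling$min[["temp_cold"]])
    rcq <- responseCurve(m, "temp_cold", nPoints = 200)
    step <- diff(rcq$value[1:2])
    expect_lt(abs(rcq$value[which.max(rcq$meanP)] - vertex), 2 * step)
  }
  expect_error(responseCurve(m, "nope"), "not in model")
})
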