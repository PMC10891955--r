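test_that("the MTSPS threshold equals the brute-force candidate scan", {
  p <- c(0.9, 0.8, 0.4)
  b <- c(0.3, 0.5, 0.2)
  thr <- mtspsThreshold(p, b)
  expect_equal(thr$mtsps, bruteMTSPS(p, b))
  expect_equal(thr$sensitivity, mean(p >= thr$mtsps))
  expect_equal(thr$specificity, mean(b < thr$mtsps))

  # perfect separation: smallest maximizing unique score
  thr2 <- mtspsThreshold(c(0.7, 0.8, 0.9), c(0.1, 0.2, 0.3))
  expect_equal(thr2$mtsps, 0.7)
  expect_equal(thr2$sensitivity + thr2$specificity, 2)

  # identical score distributions: optimum sum is about 1
  set.seed(701)
  s <- runif(300)
  thr3 <- mtspsThreshold(s, s)
  expect_lt(abs(thr3$sensitivity + thr3$specificity - 1), 0.01)

  for (i in 1:20) {
    np <- sample(5:500, 1); nb <- sample(5:500, 1)
    p <- round(runif(np), 2); b <- round(runif(nb) * 0.8, 2)
    expect_equal(mtspsThreshold(p, b)$mtsps, bruteMTSPS(p, b))
  }
  expect_error(mtspsThreshold(numeric(), 1), "non-empty")
})

test_that("classification follows the caption's boundary semantics exactly", {
  g <- tinyGeom(2, 3)
  P <- matrix(c(0.3, 0.3422, 0.4, 0.41, 0.6, 0.61), 2, 3)
  suit <- new("SuitabilityMap", geometry = g, values = P,
              mask = matrix(FALSE, 2, 3), transform = "cloglog",
              label = "t")
  cm <- classify(suit, 0.3422)
  expect_equal(classValues(cm)[1, 1], 0L)  # P = 0.3 is unsuitable
  expect_equal(classValues(cm)[2, 1], 0L)  # P = mtsps is unsuitable
  expect_equal(classValues(cm)[1, 2], 1L)  # P = 0.4 is low
  expect_equal(classValues(cm)[2, 2], 2L)  # P = 0.41 is medium
  expect_equal(classValues(cm)[1, 3], 2L)  # P = 0.6 is medium
  expect_equal(classValues(cm)[2, 3], 3L)  # P = 0.61 is high

  expect_error(classify(suit, 1.5), "0, 1")
  expect_message(classify(suit, 0.45), "low class is empty")
})

test_that("a full-map classification partitions the valid cells", {
  d <- smallDataset(702)
  kept <- c("temp_cold", "prec_dry")
  m <- maxentFit(d$pres[, kept], d$bgv[, kept], maxentConfig(knots = 6))
  suit <- maxentPredict(m, d$world$grid)
  cm <- classify(suit, 0.35)
  expect_equal(sum(classCounts(cm)), sum(!nodataMask(d$world$grid)))
  expect_true(all(is.na(classValues(cm)[nodataMask(d$world$grid)])))
})

test_that("projection matches prediction on the identity scenario and clamp rules", {
  d <- smallDataset(703)
  kept <- c("temp_cold", "prec_wet", "prec_dry")
  m <- maxentFit(d$pres[, kept], d$bgv[, kept], maxentConfig(knots = 6))
  ident <- applyScenario(d$world$grid,
                         scenarioSpec("same", add = c(temp_cold = 0)))
  expect_equal(suitabilityValues(project(m, ident)),
               suitabilityValues(maxentPredict(m, d$world$grid)))

  # clamped and unclamped projections differ only beyond the training range
  warm <- applyScenario(d$world$grid,
                        scenarioSpec("hot", add = c(temp_cold = 30)))
  on <- project(m, warm, clamp = TRUE)
  off <- project(m, warm, clamp = FALSE)
  tempWarm <- bandValues(warm, "temp_cold")
  inRange <- !nodataMask(warm) & tempWarm <= m@scaling$max[["temp_cold"]]
  expect_equal(suitabilityValues(on)[inRange],
               suitabilityValues(off)[inRange])
})

test_that("warming beyond the thermal optimum lowers suitability there", {
  d <- smallDataset(704, n = 150, bgN = 900, nrow = 50, ncol = 50)
  kept <- c("temp_cold", "prec_wet", "prec_dry")
  m <- maxentFit(d$pres[, kept], d$bgv[, kept], maxentConfig(knots = 8))
  cur <- maxentPredict(m, d$world$grid)
  # region sitting at the upper edge of the planted 15-25 degree plateau
  temp <- bandValues(d$world$grid, "temp_cold")
  region <- !nodataMask(d$world$grid) & temp >= 22 & temp <= 25
  skip_if(sum(region) < 25)
  warm <- applyScenario(d$world$grid,
                        scenarioSpec("plus2", add = c(temp_cold = 2)))
  fut <- project(m, warm)
  expect_lt(mean(suitabilityValues(fut)[region]),
            mean(suitabilityValues(cur)[region]))
})

test_that("change summaries conserve cells and detect single transitions", {
  g <- tinyGeom(4, 4)
  mk <- function(cl) new("ClassifiedMap", geometry = g,
                         classes = cl,
                         thresholds = c(mtsps = 0.3, low = 0.4,
                                        medium = 0.6), label = "x")
  set.seed(705)
  a <- matrix(sample(0:3, 16, replace = TRUE), 4, 4)
  same <- changeSummary(mk(a), mk(a))
  expect_true(all(same$transitions[row(same$transitions) !=
                                     col(same$transitions)] == 0))
  expect_equal(unname(same$netChange), rep(0L, 4))

  b <- a
  iLow <- which(a == 1)[1]
  b[iLow] <- 3L
  one <- changeSummary(mk(a), mk(b))
  expect_equal(one$transitions["low", "high"],
               sum(a == 1 & b == 3))
  expect_equal(sum(one$transitions), 16)

  for (i in 1:10) {
    x <- matrix(sample(0:3, 16, replace = TRUE), 4, 4)
    y <- matrix(sample(0:3, 16, replace = TRUE), 4, 4)
    cs <- changeSummary(mk(x), mk(y))
    # independent per-map tallies
    expect_equal(unname(rowSums(cs$transitions)),
                 vapply(0:3, function(k) sum(x == k), numeric(1)))
    expect_equal(unname(colSums(cs$transitions)),
                 vapply(0:3, function(k) sum(y == k), numeric(1)))
  }
  g2 <- tinyGeom(4, 4, cellSize = 2)
  expect_error(changeSummary(mk(a), new("ClassifiedMap", geometry = g2,
                                        classes = a,
                                        thresholds = c(mtsps = 0.3,
                                                       low = 0.4,
                                                       medium = 0.6),
                                        label = "y")),
               class = "nichecast_alignment_error")
})
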