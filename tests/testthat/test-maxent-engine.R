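test_that("feature expansion honours the scaling and knot definitions", {
  set.seed(401)
  bg <- cbind(a = runif(200, 10, 30), b = runif(200, 0, 5))
  pres <- bg[1:100, ]
  fb <- buildFeatures(pres, bg, maxentConfig(knots = 4))
  # linear feature of a variable at its background max is exactly 1
  iMax <- which.max(bg[, "a"])
  la <- which(fb$defs$class == "linear" & fb$defs$var1 == "a")
  expect_equal(fb$bgF[iMax, la], 1)
  expect_equal(min(fb$bgF[, la]), 0)
  # threshold indicator: scaled 0.4 under knot 0.5 gives 0
  sa <- (bg[, "a"] - min(bg[, "a"])) / diff(range(bg[, "a"]))
  th <- which(fb$defs$class == "threshold" & fb$defs$var1 == "a")
  for (k in th)
    expect_equal(fb$bgF[, k], as.numeric(sa > fb$defs$knot[k]))
  # hinge endpoints: 0 at its knot, 1 at the background max
  hf <- which(fb$defs$class == "hinge" & !fb$defs$reverse &
                fb$defs$var1 == "a")[1]
  atKnot <- which.min(abs(sa - fb$defs$knot[hf]))
  expect_lt(fb$bgF[atKnot, hf], 0.05)
  expect_equal(fb$bgF[iMax, hf], 1)
})

test_that("auto feature selection gates classes by presence count", {
  set.seed(402)
  bg <- cbind(x = runif(300), y = runif(300))
  cfg <- maxentConfig()
  expect_setequal(buildFeatures(bg[1:8, ], bg, cfg)$classes, "linear")
  expect_setequal(buildFeatures(bg[1:12, ], bg, cfg)$classes,
                  c("linear", "quadratic"))
  expect_setequal(buildFeatures(bg[1:20, ], bg, cfg)$classes,
                  c("linear", "quadratic", "hinge"))
  expect_setequal(buildFeatures(bg[1:100, ], bg, cfg)$classes,
                  c("linear", "quadratic", "hinge", "threshold", "product"))
})

test_that("null data yields the null model: beta = 0, gain = 0", {
  # presences identical to the whole background, uniform weights
  bg <- cbind(x = seq(0, 1, length.out = 16))
  m <- suppressWarnings(maxentFit(bg, bg, maxentConfig(knots = 3,
                                                       autoFeatures = FALSE)))
  expect_equal(unname(m@beta), rep(0, length(m@beta)))
  expect_equal(regularizedGain(m), 0)
})

test_that("coordinate descent matches dense grid search on tiny instances", {
  # one binary feature over a 4-cell background, presences on feature = 1
  presF <- matrix(1, 6, 1)
  bgF <- matrix(c(1, 1, 0, 0), 4, 1)
  lambda <- 0.05
  fit <- maxentCoreFit(presF, bgF, lambda, tol = 1e-12, maxPasses = 5000)
  grid <- seq(-10, 10, by = 1e-3)
  objs <- vapply(grid, function(b) bruteObjective(b, presF, bgF, lambda),
                 numeric(1))
  expect_lt(abs(fit$beta - grid[which.min(objs)]), 2e-3)

  # two-feature instances (one continuous, one binary, so the objective has
  # a well-defined minimizer) against a refined two-stage dense scan
  set.seed(403)
  for (rep in 1:3) {
    bgF2 <- cbind(runif(12), rbinom(12, 1, 0.5))
    presF2 <- cbind(runif(7, 0.4, 1), rbinom(7, 1, 0.7))
    lam2 <- c(0.03, 0.08)
    fit2 <- maxentCoreFit(presF2, bgF2, lam2, tol = 1e-12, maxPasses = 20000)
    coarse <- seq(-10, 10, by = 0.05)
    og <- outer(coarse, coarse, Vectorize(function(b1, b2)
      bruteObjective(c(b1, b2), presF2, bgF2, lam2)))
    ix <- which(og == min(og), arr.ind = TRUE)[1, ]
    fine1 <- seq(coarse[ix[1]] - 0.06, coarse[ix[1]] + 0.06, by = 1e-3)
    fine2 <- seq(coarse[ix[2]] - 0.06, coarse[ix[2]] + 0.06, by = 1e-3)
    of <- outer(fine1, fine2, Vectorize(function(b1, b2)
      bruteObjective(c(b1, b2), presF2, bgF2, lam2)))
    jx <- which(of == min(of), arr.ind = TRUE)[1, ]
    expect_lt(abs(fit2$beta[1] - fine1[jx[1]]), 2e-3)
    expect_lt(abs(fit2$beta[2] - fine2[jx[2]]), 2e-3)
  }
})

test_that("the optimizer's gain trace is monotone and raw output normalizes", {
  d <- smallDataset(404)
  kept <- c("temp_cold", "prec_dry")
  m <- maxentFit(d$pres[, kept], d$bgv[, kept], maxentConfig(knots = 8))
  expect_gte(regularizedGain(m), 0)
  expect_true(all(diff(m@gainTrace) >= -1e-12))
  raw <- maxentPredict(m, d$bgv[, kept], transform = "raw")
  expect_lt(abs(sum(raw) - 1), 1e-8)
})

test_that("stronger regularization never grows the L1 norm", {
  set.seed(405)
  for (i in 1:100) {
    n <- sample(10:30, 1)
    nf <- sample(2:4, 1)
    bgF <- matrix(runif(n * nf), n, nf)
    presF <- matrix(runif(8 * nf)^0.5, 8, nf)
    base <- runif(1, 0.01, 0.2)
    b1 <- maxentCoreFit(presF, bgF, rep(base, nf), tol = 1e-10,
                        maxPasses = 5000)$beta
    b2 <- maxentCoreFit(presF, bgF, rep(2 * base, nf), tol = 1e-10,
                        maxPasses = 5000)$beta
    expect_lte(sum(abs(b2)), sum(abs(b1)) + 1e-6)
  }
})

test_that("predictions transform correctly and respect clamping", {
  d <- smallDataset(406)
  kept <- c("temp_cold", "prec_wet")
  m <- maxentFit(d$pres[, kept], d$bgv[, kept], maxentConfig(knots = 8))
  # beyond-range prediction equals the range-edge prediction when clamped
  hi <- cbind(temp_cold = m@scaling$max[["temp_cold"]] + 50,
              prec_wet = m@scaling$max[["prec_wet"]] + 500)
  edge <- cbind(temp_cold = m@scaling$max[["temp_cold"]],
                prec_wet = m@scaling$max[["prec_wet"]])
  expect_equal(maxentPredict(m, hi, clamp = TRUE),
               maxentPredict(m, edge, clamp = TRUE))
  # an unpenalized-uniform model predicts one constant cloglog value
  null <- suppressWarnings(
    maxentFit(d$bgv[, kept], d$bgv[, kept],
              maxentConfig(knots = 3, autoFeatures = FALSE)))
  p <- maxentPredict(null, d$bgv[1:50, kept], transform = "cloglog")
  expect_lt(diff(range(p)), 1e-10)
  # background order must not matter
  perm <- sample(nrow(d$bgv))
  m2 <- maxentFit(d$pres[, kept], d$bgv[perm, kept],
                  maxentConfig(knots = 8))
  expect_lt(max(abs(maxentPredict(m2, d$bgv[1:100, kept]) -
                    maxentPredict(m, d$bgv[1:100, kept]))), 1e-10)
})

test_that("percent contribution is a normalized per-variable gain ledger", {
  d <- smallDataset(407)
  single <- maxentFit(d$pres[, "temp_cold", drop = FALSE],
                      d$bgv[, "temp_cold", drop = FALSE],
                      maxentConfig(knots = 8))
  expect_equal(unname(percentContribution(single)), 100)

  # two independent, equally informative copies split the credit
  set.seed(408)
  bg2 <- cbind(u = runif(500), v = runif(500))
  pres2 <- cbind(u = runif(60, 0.6, 1), v = runif(60, 0.6, 1))
  pc <- percentContribution(maxentFit(pres2, bg2, maxentConfig(knots = 8)))
  expect_equal(sum(pc), 100, tolerance = 0.1)
  expect_lt(abs(pc[["u"]] - 50), 10)

  pcAll <- percentContribution(maxentFit(d$pres, d$bgv,
                                         maxentConfig(knots = 6)))
  expect_equal(sum(pcAll), 100, tolerance = 0.1)
})

test_that("a serialized model reproduces predictions bit for bit", {
  d <- smallDataset(409)
  kept <- c("temp_cold", "prec_dry")
  m <- maxentFit(d$pres[, kept], d$bgv[, kept], maxentConfig(knots = 6),
                 seed = 409)
  path <- file.path(withr::local_tempdir(), "model.json")
  modelToJSON(m, path)
  back <- modelFromJSON(path)
  expect_identical(maxentPredict(back, d$bgv[, kept]),
                   maxentPredict(m, d$bgv[, kept]))
  expect_equal(back@gain, m@gain)
  expect_error(maxentPredict(m, d$bgv[, "temp_cold", drop = FALSE]),
               "missing variable")
})
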