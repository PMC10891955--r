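test_that("generated fields honour the target correlation structure", {
  g50 <- gridGeometry(50, 50, xOrigin = 0, yOrigin = 50, cellSize = 1)
  grid <- makeEnvGrid(g50, 3, smoothness = 2, seed = 201)
  ac <- attr(grid, "achievedCorr")
  expect_lt(max(abs(ac[upper.tri(ac)])), 0.15)

  g100 <- gridGeometry(100, 100, xOrigin = 0, yOrigin = 100, cellSize = 1)
  C <- diag(3); C[1, 2] <- C[2, 1] <- 0.95
  grid2 <- makeEnvGrid(g100, 3, smoothness = 3, targetCorr = C, seed = 202)
  expect_lt(abs(attr(grid2, "achievedCorr")[1, 2] - 0.95), 0.05)

  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(makeEnvGrid(g50, 3, targetCorr = bad, seed = 1),
               "positive semi-definite")

  again <- makeEnvGrid(g50, 3, smoothness = 2, seed = 201)
  expect_identical(grid@values, again@values)
})

test_that("true suitability reproduces the planted response shapes", {
  g <- tinyGeom(4, 4)
  vals <- matrix(c(rep(20, 8), rep(5, 8)), 4, 4)  # half inside plateau
  grid <- envGrid(g, list(temp = vals))
  niche <- nicheSpec(temp = nicheResponse("plateau_unimodal", lower = 15,
                                          upper = 25))
  s <- trueSuitability(grid, niche)
  expect_equal(max(suitabilityValues(s)), 1)
  expect_equal(suitabilityValues(s)[1, 1], 1)      # inside the plateau
  expect_lt(suitabilityValues(s)[1, 4], 0.01)      # far below it

  # no precipitation in the driest month means zero suitability
  dry <- envGrid(g, list(prec = matrix(c(0, rep(100, 15)), 4, 4)))
  sd0 <- trueSuitability(dry, nicheSpec(
    prec = nicheResponse("saturating", lower = 50, upper = 150)))
  expect_equal(suitabilityValues(sd0)[1, 1], 0)
  expect_equal(suitabilityValues(sd0)[2, 2], 1)

  expect_error(trueSuitability(grid, nicheSpec(
    other = nicheResponse("peaked", peak = 1, width = 1))), "not in grid")
  expect_error(nicheSpec(a = nicheResponse("flat")), "non-flat")
})

test_that("suitability lies in [0,1] and ignores band order", {
  w <- makeDefaultWorld(seed = 203, nrow = 30, ncol = 30)
  v <- suitabilityValues(w$suitability)
  expect_gte(min(v, na.rm = TRUE), 0)
  expect_lte(max(v, na.rm = TRUE), 1)
  # permute band storage order; suitability must not move
  perm <- rev(seq_along(bandNames(w$grid)))
  bands <- lapply(perm, function(b) w$grid@values[, , b])
  names(bands) <- bandNames(w$grid)[perm]
  grid2 <- envGrid(geometry(w$grid), bands, mask = nodataMask(w$grid))
  s2 <- trueSuitability(grid2, w$niche)
  expect_equal(suitabilityValues(s2), v)
})

test_that("occurrence sampling follows the suitability weights", {
  g <- tinyGeom(3, 3)
  s <- matrix(0, 3, 3); s[2, 2] <- 1
  suit <- new("SuitabilityMap", geometry = g, values = s,
              mask = matrix(FALSE, 3, 3), transform = "true", label = "t")
  one <- records(sampleOccurrences(suit, 1, seed = 204))
  expect_equal(c(one$lon, one$lat), c(1.5, 1.5))

  uni <- new("SuitabilityMap", geometry = g, values = matrix(1, 3, 3),
             mask = matrix(FALSE, 3, 3), transform = "true", label = "t")
  all9 <- records(sampleOccurrences(uni, 9, seed = 205))
  expect_equal(nrow(unique(all9[, c("lon", "lat")])), 9)
  expect_error(sampleOccurrences(uni, 10, seed = 1), "exceeds")

  # 0.8 / 0.2 two-cell surface, with replacement: frequency ratio ~ 4:1
  two <- new("SuitabilityMap", geometry = tinyGeom(1, 2),
             values = matrix(c(0.8, 0.2), 1, 2),
             mask = matrix(FALSE, 1, 2), transform = "true", label = "t")
  draws <- records(sampleOccurrences(two, 10000, seed = 206,
                                     replace = TRUE))
  phat <- mean(draws$lon < 1)
  expect_lt(abs(phat - 0.8), 3 * sqrt(0.8 * 0.2 / 10000) + 1e-9)

  zero <- new("SuitabilityMap", geometry = g, values = matrix(0, 3, 3),
              mask = matrix(FALSE, 3, 3), transform = "true", label = "t")
  expect_error(sampleOccurrences(zero, 1, seed = 1), "zero everywhere")
})

test_that("scenario perturbations act bandwise and commute with cropping", {
  w <- makeDefaultWorld(seed = 207, nrow = 20, ncol = 20)
  sc <- scenarioSpec("warm2", add = c(temp_cold = 2),
                     mult = c(prec_wet = 0.5))
  out <- applyScenario(w$grid, sc)
  d <- bandValues(out, "temp_cold") - bandValues(w$grid, "temp_cold")
  expect_equal(unname(d[!nodataMask(w$grid)]),
               rep(2, sum(!nodataMask(w$grid))))
  expect_equal(bandValues(out, "prec_wet"),
               bandValues(w$grid, "prec_wet") * 0.5)

  ident <- applyScenario(w$grid, scenarioSpec("same", add = c(temp_cold = 0),
                                              mult = c(prec_wet = 1)))
  expect_equal(ident@values, w$grid@values)
  expect_error(applyScenario(w$grid, scenarioSpec("x", add = c(nope = 1))),
               "not in grid")
  expect_error(scenarioSpec("x", mult = c(prec_wet = -1)), "positive")
  expect_error(scenarioSpec(""), "non-empty")

  # crop-then-perturb equals perturb-then-crop
  crop <- function(grid, rows, cols) {
    bands <- lapply(seq_along(bandNames(grid)),
                    function(b) grid@values[rows, cols, b])
    names(bands) <- bandNames(grid)
    g <- geometry(grid)
    envGrid(gridGeometry(length(rows), length(cols),
                         xOrigin = g@xOrigin + (min(cols) - 1) * g@cellSize,
                         yOrigin = g@yOrigin - (min(rows) - 1) * g@cellSize,
                         cellSize = g@cellSize),
            bands, mask = nodataMask(grid)[rows, cols])
  }
  a <- applyScenario(crop(w$grid, 5:15, 3:12), sc)
  b <- crop(applyScenario(w$grid, sc), 5:15, 3:12)
  expect_equal(a@values, b@values)
})

test_that("packaged fixtures load intact and match the printed entries", {
  fx <- loadPaperFixtures()
  expect_equal(dim(fx$correlation), c(20, 20))
  expect_equal(unname(diag(fx$correlation)), rep(1, 20))
  expect_equal(fx$correlation["bio11", "bio3"], 0.95)
  expect_equal(fx$correlation["bio4", "bio11"], -0.96)
  expect_equal(unname(fx$contributions["bio8"]), 0.1)
  expect_equal(unname(fx$contributions["bio18"]), 0.6)
  expect_true(all(fx$contributions >= 0))
  expect_equal(names(fx$finalContributions), c("bio11", "bio13", "bio14"))
})
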