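test_that("summed current at fixes matches the per-fix loop oracle and its
           degenerate cases", {
  set.seed(61)
  cm <- rasterGrid(matrix(runif(100), 10, 10))
  # n fixes in one cell of value c -> n c
  fx <- data.frame(x_km = rep(3.5, 4), y_km = rep(6.5, 4))
  c1 <- gridValues(cm)[cellFromXY(cm, 3.5, 6.5)]
  expect_equal(as.numeric(scoreScenario(cm, fx)), 4 * c1)
  expect_equal(as.numeric(scoreScenario(cm, fx[0, ])), 0)
  fx2 <- data.frame(x_km = runif(30, 0, 10), y_km = runif(30, 0, 10))
  oracle <- sum(vapply(seq_len(30), function(i) {
    rc <- cellFromXY(cm, fx2$x_km[i], fx2$y_km[i])
    gridValues(cm)[rc[1, 1], rc[1, 2]]
  }, numeric(1)))
  expect_equal(as.numeric(scoreScenario(cm, fx2)), oracle)
  # nodata fix contributes zero, with a message
  cm2 <- cm; v <- gridValues(cm2); v[7, 4] <- NA; gridValues(cm2) <- v
  expect_message(s <- scoreScenario(cm2, data.frame(x_km = 3.5, y_km = 3.5)),
                 "nodata")
  expect_equal(as.numeric(s), 0)
})

test_that("individual ranking orders by summed current, applies the fixed
           tie-break and demands all five maps", {
  mk <- function(val) rasterGrid(matrix(val, 2, 2))
  maps <- list(r0 = mk(5), r1 = mk(4), r2 = mk(3), r3 = mk(10), r4 = mk(2))
  fx <- data.frame(x_km = 0.5, y_km = 0.5)
  rk <- rankIndividual(maps, fx, id = "a")
  expect_equal(rk$top, "r3")
  expect_equal(names(rk$scores), c("r3", "r0", "r1", "r2", "r4"))
  expect_false(rk$tie)
  # exact tie r3 = r4: fixed order prefers r3, tie flagged
  maps2 <- list(r0 = mk(1), r1 = mk(1), r2 = mk(1), r3 = mk(8), r4 = mk(8))
  rk2 <- rankIndividual(maps2, fx)
  expect_true(rk2$tie)
  expect_equal(rk2$top, "r3")
  expect_error(rankIndividual(maps[-3], fx), "missing scenario map")
})

test_that("support tabulation closes to proportion one", {
  rks <- list(list(top = "r3"), list(top = "r3"), list(top = "r4"),
              list(top = "r3"))
  tab <- tabulateSupport(rks)
  expect_equal(sum(tab$proportion), 1)
  expect_equal(tab$proportion[tab$scenario == "r3"], 0.75)
  expect_equal(tab$count[tab$scenario == "r2"], 0)
})

test_that("population maps sum to the number of individuals, are linear in
           duplicated maps and permutation-invariant", {
  set.seed(63)
  mk <- function() rasterGrid(matrix(runif(64, 0.1, 1), 8, 8))
  one <- mk()
  p1 <- populationMap(list(one))
  expect_equal(sum(gridValues(p1@raster)), 1, tolerance = 1e-12)
  p2 <- populationMap(list(one, one))
  expect_equal(gridValues(p2@raster), 2 * gridValues(p1@raster),
               tolerance = 1e-12)
  maps <- replicate(50, mk(), simplify = FALSE)
  pn <- populationMap(maps)
  expect_lt(abs(sum(gridValues(pn@raster)) - 50), 1e-9)
  perm <- populationMap(maps[sample(50)])
  expect_equal(gridValues(pn@raster), gridValues(perm@raster),
               tolerance = 1e-12)
  zero <- rasterGrid(matrix(0, 8, 8))
  expect_error(populationMap(list(zero)), "zero total current")
})

test_that("ranking is invariant only under a common positive rescaling of
           all scenario maps", {
  set.seed(65)
  mk <- function() rasterGrid(matrix(runif(64, 0.1, 1), 8, 8))
  maps <- list(r0 = mk(), r1 = mk(), r2 = mk(), r3 = mk(), r4 = mk())
  fx <- data.frame(x_km = runif(10, 0, 8), y_km = runif(10, 0, 8))
  base <- rankIndividual(maps, fx)
  scaled <- lapply(maps, function(m) {
    m@values <- m@values * 7.3
    m
  })
  expect_equal(rankIndividual(scaled, fx)$scores / 7.3, base$scores,
               tolerance = 1e-12)
  expect_equal(rankIndividual(scaled, fx)$top, base$top)
})

test_that("a uniform population map validates with fix mean equal to area
           mean; corridor-structured maps validate with high rho", {
  # uniform maps: mean at fixes equals the study-area mean exactly
  uni <- replicate(4, rasterGrid(matrix(1, 10, 10)), simplify = FALSE)
  fx <- replicate(4, data.frame(x_km = runif(20, 0, 10),
                                y_km = runif(20, 0, 10)), simplify = FALSE)
  suppressWarnings(v <- validatePopulationMap(uni, fx, k = 2, seed = 1))
  expect_equal(v$mean_at_fixes, v$mean_study_area)
  # corridor maps: current decays smoothly away from a central band and
  # fixes concentrate around the corridor axis
  set.seed(67)
  mkCorr <- function() {
    m <- outer(rep(1, 20), exp(-abs(1:20 - 10) / 3)) *
      matrix(runif(400, 0.8, 1.2), 20, 20)
    rasterGrid(m)
  }
  maps <- replicate(10, mkCorr(), simplify = FALSE)
  fxs <- replicate(10, data.frame(
    x_km = pmin(pmax(rnorm(40, 9.5, 2), 0.1), 19.9),
    y_km = runif(40, 0, 20)), simplify = FALSE)
  vc <- validatePopulationMap(maps, fxs, k = 5, seed = 2)
  expect_gte(vc$mean_rho, 0.8)
  expect_gt(vc$mean_at_fixes, vc$mean_study_area)
  expect_warning(validatePopulationMap(maps[1:3], fxs[1:3], k = 10, seed = 1),
                 "reducing k")
})
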