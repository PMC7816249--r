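test_that("landscape and track generation are bit-identical under one seed
           and differ under another", {
  cfg <- simulationConfig(seed = 1, nAnimals = 2)
  b1 <- generateLandscape(cfg, extent = c(0, 30, 0, 30))
  b2 <- generateLandscape(cfg, extent = c(0, 30, 0, 30))
  expect_identical(gridValues(b1@elevation), gridValues(b2@elevation))
  expect_identical(b1@rivers, b2@rivers)
  b3 <- generateLandscape(simulationConfig(seed = 2, nAnimals = 2),
                          extent = c(0, 30, 0, 30))
  expect_false(identical(gridValues(b1@elevation), gridValues(b3@elevation)))
  res <- rasterGrid(matrix(1, 30, 30))
  t1 <- simulateTracks(b1, res, cfg)
  t2 <- simulateTracks(b1, res, cfg)
  expect_identical(lapply(t1, trackFixes), lapply(t2, trackFixes))
})

test_that("generated landcover holds all four classes with open most
           frequent, and flat terrain yields zero ruggedness downstream", {
  cfg <- simulationConfig(seed = 4)
  b <- generateLandscape(cfg, extent = c(0, 50, 0, 50))
  tab <- table(gridValues(b@landcover))
  expect_setequal(as.integer(names(tab)), 0:3)
  expect_equal(as.integer(names(which.max(tab))), 0)
  flat <- generateLandscape(cfg, extent = c(0, 30, 0, 30), flat = TRUE)
  v <- gridValues(vectorRuggedness(flat@elevation))
  expect_true(all(v[is.finite(v)] == 0))
  expect_error(generateLandscape(cfg, extent = c(0, 1, 0, 30)), "degenerate")
})

test_that("track timestamps advance by exactly the fix interval and
           endpoints sit inside the start/end regions", {
  s <- smallStudy(seed = 6, nAnimals = 3)
  tracks <- simulateTracks(s$bundle, s$res@raster, s$cfg)
  ext <- s$bundle@extent
  w <- ext[2] - ext[1]; h <- ext[4] - ext[3]
  for (tr in tracks) {
    f <- trackFixes(tr)
    expect_true(all(diff(as.numeric(f$timestamp)) == 8 * 3600))
    expect_gte(f$y_km[1], ext[3] + 0.05 * h - 1e-9)
    expect_lte(f$y_km[1], ext[3] + 0.18 * h + 1e-9)
    expect_gte(f$y_km[nrow(f)], ext[4] - 0.18 * h - 1e-9)
  }
})

test_that("with zero selection strength and no goal bias, step directions
           are uniform over the 8 neighbours (chi-square)", {
  cfg <- simulationConfig(seed = 8, nAnimals = 6, residencyDuration = 2,
                          migrationDuration = 400, selectionStrength = 0,
                          goalBias = 0)
  b <- generateLandscape(cfg, extent = c(0, 60, 0, 60), flat = TRUE)
  res <- rasterGrid(matrix(1, 60, 60))
  tracks <- suppressWarnings(simulateTracks(b, res, cfg))
  # collect interior steps only: edge cells restrict the neighbour set
  steps <- c()
  for (tr in tracks) {
    f <- trackFixes(tr)
    dx <- round(diff(f$x_km)); dy <- round(diff(f$y_km))
    interior <- f$x_km[-nrow(f)] > 3 & f$x_km[-nrow(f)] < 57 &
      f$y_km[-nrow(f)] > 3 & f$y_km[-nrow(f)] < 57 & (dx != 0 | dy != 0)
    steps <- c(steps, paste(dx[interior], dy[interior]))
  }
  counts <- table(factor(steps, levels = c("-1 -1", "-1 0", "-1 1", "0 -1",
                                           "0 1", "1 -1", "1 0", "1 1")))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("strong selection on a single low-resistance corridor keeps most
           migration fixes inside the corridor band", {
  # uniform high resistance except a vertical corridor of width 5 km
  nr <- 60; nc <- 60
  m <- matrix(100, nr, nc)
  m[, 28:32] <- 1
  res <- rasterGrid(m)
  cfg <- simulationConfig(seed = 10, nAnimals = 100, residencyDuration = 2,
                          migrationDuration = 400, selectionStrength = 4,
                          goalBias = 1,
                          startRegion = c(25, 35, 1, 6),
                          endRegion = c(25, 35, 54, 59))
  b <- generateLandscape(cfg, extent = c(0, 60, 0, 60), flat = TRUE)
  tracks <- simulateTracks(b, res, cfg)
  inCorr <- 0; tot <- 0
  for (tr in tracks) {
    w <- detectMigration(tr)
    if (is.null(w)) next
    f <- trackFixes(tr)[w@startIndex:w@endIndex, ]
    inCorr <- inCorr + sum(f$x_km >= 27 & f$x_km <= 32)
    tot <- tot + nrow(f)
  }
  expect_gt(inCorr / tot, 0.8)
})

test_that("mean resistance at migration fixes is below the study-area mean
           when selection strength is positive", {
  s <- smallStudy(seed = 12, nAnimals = 50, extent = c(0, 40, 0, 40))
  # a rare walker may hit the step cap and warn; irrelevant to the property
  tracks <- suppressWarnings(simulateTracks(s$bundle, s$res@raster, s$cfg))
  rvals <- c()
  for (tr in tracks) {
    w <- detectMigration(tr)
    if (is.null(w)) next
    f <- trackFixes(tr)[w@startIndex:w@endIndex, ]
    rvals <- c(rvals, valuesAtXY(s$res@raster, f$x_km, f$y_km))
  }
  areaMean <- mean(gridValues(s$res@raster)[is.finite(gridValues(s$res@raster))])
  expect_lt(mean(rvals, na.rm = TRUE), areaMean)
  # one-sided t-test against the area mean
  expect_lt(stats::t.test(rvals, mu = areaMean,
                          alternative = "less")$p.value, 0.01)
})
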