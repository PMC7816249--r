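test_that("VRM is zero for flat and uniformly tilted terrain", {
  flat <- rasterGrid(matrix(250, 8, 8))
  v <- gridValues(vectorRuggedness(flat))
  expect_true(all(v[is.finite(v)] == 0))
  # border cells whose window leaves the raster are nodata, not zero
  expect_true(all(is.na(v[1:2, ])) && all(is.na(v[, 1:2])))
  # uniform plane: all normals parallel regardless of tilt
  plane <- rasterGrid(outer(1:10, 1:10, function(r, c) 30 * r + 12 * c))
  vp <- gridValues(vectorRuggedness(plane))
  expect_lt(max(vp[is.finite(vp)]), 1e-12)
})

test_that("VRM matches an explicit loop-based recomputation on rough
           terrain, is bounded in [0,1] and shift-invariant", {
  set.seed(11)
  e <- matrix(rnorm(144, 0, 80), 12, 12)
  g <- rasterGrid(e, cellSize = 0.1)
  vrm <- gridValues(vectorRuggedness(g))
  # independent oracle: per-cell loops over the 9 normals
  cs_m <- 0.1 * 1000
  normalAt <- function(i, j) {
    sub <- e[(i - 1):(i + 1), (j - 1):(j + 1)]
    zx <- ((sub[1, 3] + 2 * sub[2, 3] + sub[3, 3]) -
           (sub[1, 1] + 2 * sub[2, 1] + sub[3, 1])) / (8 * cs_m)
    zy <- ((sub[1, 1] + 2 * sub[1, 2] + sub[1, 3]) -
           (sub[3, 1] + 2 * sub[3, 2] + sub[3, 3])) / (8 * cs_m)
    sl <- atan(sqrt(zx^2 + zy^2)); asp <- atan2(zy, zx)
    if (sl == 0) c(0, 0, 1) else
      c(sin(sl) * sin(asp), sin(sl) * cos(asp), cos(sl))
  }
  for (i in c(3, 6, 10)) for (j in c(3, 7, 10)) {
    acc <- c(0, 0, 0)
    for (di in -1:1) for (dj in -1:1)
      acc <- acc + normalAt(i + di, j + dj)
    expect_equal(vrm[i, j], 1 - sqrt(sum(acc^2)) / 9, tolerance = 1e-12)
  }
  fin <- vrm[is.finite(vrm)]
  expect_true(all(fin >= 0 & fin <= 1))
  shifted <- gridValues(vectorRuggedness(rasterGrid(e + 1234, cellSize = 0.1)))
  expect_equal(vrm, shifted, tolerance = 1e-9)
})

test_that("road decay follows exp(-alpha/d): anchor value, limits,
           scale invariance and monotonicity along a ray", {
  g <- rasterGrid(matrix(0, 1, 201), cellSize = 1)  # row of cells, y = 0.5
  road <- list(cbind(c(0.5, 0.5), c(-10, 10)))      # vertical line at x=0.5
  rd60 <- roadDecay(road, g, alpha = 60)$decay
  v60 <- gridValues(rd60)[1, ]
  d <- xyFromCell(g, rep(1, 201), 1:201)[, 1] - 0.5
  # alpha = d = 60 gives exp(-1)
  expect_equal(v60[d == 60], exp(-1), tolerance = 1e-12)
  # on the road the limit value is 0
  expect_equal(v60[1], 0)
  # monotone increasing with distance
  expect_true(all(diff(v60) > 0))
  # alpha=14 at d=14 equals alpha=60 at d=60 (scale invariance)
  rd14 <- roadDecay(road, g, alpha = 14)$decay
  expect_equal(gridValues(rd14)[1, which(d == 14)], exp(-1),
               tolerance = 1e-12)
  # far-field limit: > 0.99 at d > 100 alpha
  gg <- rasterGrid(matrix(0, 1, 1), xmin = 150, cellSize = 1)
  far <- roadDecay(road, gg, alpha = 1)$decay
  expect_gt(gridValues(far)[1, 1], 0.99)
  expect_error(roadDecay(list(), g, 60), "empty road set")
  expect_error(roadDecay(road, g, -1), "alpha")
})

test_that("the covariate stack is co-registered, standardized and carries
           all four classes from the generated landscape", {
  s <- smallStudy(seed = 3)
  st <- s$stack
  z <- gridValues(st@ruggedness_z)
  z <- z[is.finite(z)]
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sd(z) - 1), 1e-6)
  rd <- gridValues(st@road_decay)
  expect_true(all(rd[is.finite(rd)] >= 0 & rd[is.finite(rd)] < 1))
  expect_setequal(unique(as.vector(gridValues(st@landcover))), 0:3)
  # grain equal to native size is a pass-through of the landcover layer
  expect_identical(gridValues(st@landcover), gridValues(s$bundle@landcover))
})

test_that("covariate extraction returns the open-reference landcover factor
           and NA outside the valid area", {
  s <- smallStudy(seed = 3)
  df <- extractCovariates(s$stack, c(20, -5), c(20, 20))
  expect_s3_class(df$landcover, "factor")
  expect_identical(levels(df$landcover),
                   c("open", "dense", "burned", "coastal"))
  expect_true(is.na(df$ruggedness_z[2]))
})
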