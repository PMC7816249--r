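test_that("AICc reproduces its closed form, approaches AIC as n grows and
           penalises extra parameters at equal likelihood", {
  expect_equal(aicc(-50, 3, 100), 106.25)
  aic <- -2 * (-200) + 2 * 5
  expect_lt(abs(aicc(-200, 5, 1e7) - aic), 1e-3)
  expect_lt(aicc(-100, 2, 50), aicc(-100, 3, 50))
  expect_error(aicc(-10, 5, 6), "n > k")
})

test_that("availability sampling delivers ratio x n points inside the area,
           reproducibly by seed", {
  area <- c(0, 10, 5, 25)
  a <- sampleAvailability(area, nUsed = 10, seed = 1)
  expect_equal(nrow(a), 200)
  expect_true(all(a$x_km >= 0 & a$x_km <= 10 & a$y_km >= 5 & a$y_km <= 25))
  expect_identical(a, sampleAvailability(area, nUsed = 10, seed = 1))
  expect_false(identical(a, sampleAvailability(area, nUsed = 10, seed = 2)))
  one <- sampleAvailability(area, nUsed = 1, ratio = 1, seed = 3)
  expect_equal(nrow(one), 1)
  expect_error(sampleAvailability(area, nUsed = 0), "used point")
})

test_that("the factorial candidate set enumerates all unique subsets plus
           the intercept-only model", {
  fs <- candidateModelSet()
  expect_length(fs, 16)
  expect_length(unique(vapply(fs, function(f) paste(deparse(f), collapse = ""),
                              character(1))), 16)
  expect_length(candidateModelSet(c("ruggedness", "river")), 4)
})

test_that("VIF matches closed forms and flags exact collinearity", {
  set.seed(41)
  X <- matrix(rnorm(300), 100, 3)
  X <- qr.Q(qr(X)) # orthogonal columns
  expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-3)
  # correlated pair with known r
  n <- 2e5
  z <- rnorm(n)
  x1 <- z; x2 <- 0.6 * z + sqrt(1 - 0.36) * rnorm(n)
  v <- vif(cbind(x1, x2))
  expect_equal(unname(v), rep(1 / (1 - 0.36), 2), tolerance = 0.02)
  expect_true(all(is.infinite(vif(cbind(x1, x1)))))
})

test_that("an intercept-only fit on a 1:20 used-available table estimates
           log(1/20), and duplicated covariates are rejected", {
  set.seed(43)
  n <- 12600
  tab <- data.frame(response = rep(c(1, 0), c(n / 21, n - n / 21)),
                    ruggedness_z = rnorm(n))
  tab$response <- sample(tab$response)
  f <- fitRSF(tab, response ~ 1)
  expect_equal(unname(f@coefficients[1]), log(1 / 20), tolerance = 0.05)
  tab$dup <- tab$ruggedness_z
  expect_error(fitRSF(tab, response ~ ruggedness_z + dup), "rank-deficient")
})

test_that("known logistic coefficients are recovered within 3 SE at
           n = 50,000", {
  set.seed(45)
  n <- 50000
  x <- rnorm(n)
  p <- stats::plogis(-3 + 0.5 * x)
  tab <- data.frame(response = rbinom(n, 1, p), ruggedness_z = x)
  f <- fitRSF(tab, response ~ ruggedness_z)
  expect_lt(abs(f@coefficients["(Intercept)"] - (-3)) /
              f@se["(Intercept)"], 3)
  expect_lt(abs(f@coefficients["ruggedness_z"] - 0.5) /
              f@se["ruggedness_z"], 3)
})

test_that("the GLMM reduces to the fixed-effects fit when random-intercept
           variance collapses to the boundary", {
  set.seed(47)
  n <- 3000
  tab <- data.frame(response = rbinom(n, 1, stats::plogis(-2)),
                    ruggedness_z = rnorm(n),
                    animal_id = rep(sprintf("A%02d", 1:10), each = n / 10),
                    year = rep(2011:2013, length.out = n))
  fg <- suppressWarnings(fitRSF(tab, response ~ ruggedness_z,
                                randomEffects = TRUE))
  ff <- fitRSF(tab, response ~ ruggedness_z)
  # data carry no animal/year structure: variances near the zero boundary,
  # estimates agree with the fixed-effects fit
  expect_lt(max(fg@ranefVar), 0.05)
  expect_equal(unname(fg@coefficients), unname(ff@coefficients),
               tolerance = 0.01)
})

test_that("model selection ranks by AICc with weights summing to one and a
           single candidate takes weight 1", {
  set.seed(49)
  n <- 4000
  x <- rnorm(n)
  tab <- data.frame(response = rbinom(n, 1, stats::plogis(-2 + x)),
                    ruggedness_z = x, river = rbinom(n, 1, 0.2),
                    road_decay = runif(n), road_dist_km = runif(n, 0, 80),
                    landcover = factor("open",
                                       levels = c("open", "dense", "burned",
                                                  "coastal")))
  sel <- suppressWarnings(selectRSFModel(tab, candidateModelSet(
    c("ruggedness", "river", "roads"))))
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
  expect_equal(sel$table$delta_aicc[1], 0)
  expect_true(!is.unsorted(sel$table$aicc))
  # the informative covariate is in the winning model
  expect_match(sel$table$label[1], "ruggedness")
  single <- selectDecayAlpha(tab, candidates = 15)
  expect_setequal(single$label, c("alpha_15", "linear_distance"))
  expect_equal(sum(single$weight), 1, tolerance = 1e-12)
})

test_that("the default decay grid holds the 36 stated candidates", {
  g <- defaultAlphaGrid()
  expect_length(g, 36)
  expect_true(all(1:20 %in% g) && all(seq(25, 50, 5) %in% g) &&
                all(seq(60, 100, 10) %in% g) && all(seq(150, 350, 50) %in% g))
})

test_that("suitability prediction is max-normalized, monotone in a
           positive covariate, and constant for a null model", {
  s <- smallStudy(seed = 15)
  hs <- s$hs
  v <- gridValues(hs)
  expect_equal(max(v[is.finite(v)]), 1)
  expect_true(all(v[is.finite(v)] > 0))
  null <- predictSuitability(syntheticFit(c(ruggedness_z = 0)), s$stack)
  nv <- gridValues(null)
  expect_true(all(nv[is.finite(nv)] == 1))
  # multiplying all exp(lp) by a constant leaves hs unchanged: adding a
  # constant covariate shift is absorbed by normalization
  shifted <- syntheticFit(refCoefs)
  hs2 <- predictSuitability(shifted, s$stack)
  expect_equal(gridValues(hs2), gridValues(hs))
})

test_that("k-fold validation scores an informative simulated model highly
           and a pure-noise model near zero", {
  # used points rejection-sampled from exp(2 z) over the area
  set.seed(51)
  area <- c(0, 50, 0, 50)
  field <- matrix(rnorm(2500), 50, 50)
  zg <- standardizeGrid(rasterGrid(field))
  sampleUsed <- function(n, beta) {
    out <- NULL
    while (is.null(out) || nrow(out) < n) {
      x <- runif(4 * n, 0, 50); y <- runif(4 * n, 0, 50)
      z <- valuesAtXY(zg, x, y)
      acc <- runif(4 * n) < exp(beta * z) / exp(beta * max(field))
      out <- rbind(out, cbind(x, y)[acc, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  }
  mkTab <- function(beta, n = 700) {
    u <- sampleUsed(n, beta)
    a <- sampleAvailability(area, n, ratio = 20, seed = 52)
    data.frame(response = rep(c(1, 0), c(n, 20 * n)),
               ruggedness_z = c(valuesAtXY(zg, u[, 1], u[, 2]),
                                valuesAtXY(zg, a$x_km, a$y_km)))
  }
  strong <- suppressWarnings(kfoldValidate(mkTab(2), response ~ ruggedness_z,
                                           k = 5, seed = 53))
  expect_gte(strong$mean_rho, 0.9)
  # scoring on noise: rho centred near zero across replicates
  rhos <- vapply(1:12, function(i) {
    set.seed(60 + i)
    tabN <- mkTab(0, 300)
    suppressWarnings(kfoldValidate(tabN, response ~ ruggedness_z, k = 3,
                                   seed = i)$mean_rho)
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.25)
})

test_that("bootstrap response curves are seed-deterministic, collapse to
           the plug-in prediction under zero covariance, and rise with
           distance for a positive road coefficient", {
  cf <- c(ruggedness_z = -0.2, road_decay = 2.45)
  vc <- diag(c(0.01, 0.04)); dimnames(vc) <- list(names(cf), names(cf))
  fit <- new("RSFFit", coefficients = cf, se = sqrt(diag(vc)), vcov = vc,
             logLik = -10, n = 100, k = 2,
             aicc = aicc(-10, 2, 100), converged = TRUE,
             randomEffects = FALSE,
             ranefVar = setNames(numeric(0), character(0)), label = "toy")
  b1 <- bootstrapResponse(fit, alpha = 60, nBoot = 200, seed = 9)
  b2 <- bootstrapResponse(fit, alpha = 60, nBoot = 200, seed = 9)
  expect_identical(b1, b2)
  # non-decreasing everywhere (exp(-alpha/d) underflows near the road),
  # strictly increasing in the far field
  expect_true(all(diff(b1$mean) >= 0))
  expect_true(all(diff(tail(b1$mean, 50)) > 0))
  expect_true(all(b1$lo <= b1$hi))
  degenerate <- fit
  degenerate@vcov <- matrix(0, 2, 2, dimnames = dimnames(vc))
  b0 <- bootstrapResponse(degenerate, alpha = 60, nBoot = 50, seed = 1)
  plugin <- exp(2.45 * exp(-60 / b0$dist_km))
  expect_equal(b0$mean, plugin, tolerance = 1e-12)
  expect_equal(b0$lo, b0$hi, tolerance = 1e-12)
})
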