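# Used-available resource selection: availability sampling, logistic /
# mixed-model fitting, AICc-based decay and factorial model selection,
# collinearity screening, suitability prediction, k-fold validation and
# parametric-bootstrap response curves.

#' Small-sample-corrected Akaike information criterion
#'
#' @param logLik model log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations (must exceed `k + 1`).
#' @return `-2 logLik + 2k + 2k(k+1)/(n - k - 1)`.
#' @examples
#' aicc(-50, 3, 100)  # 106.25
#' @export
aicc <- function(logLik, k, n) {
  stopIfNot(n > k + 1, "AICc requires n > k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Sample available points uniformly over the study area
#'
#' @param studyArea `c(xmin, xmax, ymin, ymax)` rectangle (km), the square
#'   bounding box slightly larger than the herd's range.
#' @param nUsed number of used (observed) locations.
#' @param ratio available points per used point (default 20).
#' @param seed RNG seed (reproducible draws).
#' @return data.frame with `x_km`, `y_km` of `ratio * nUsed` points.
#' @export
sampleAvailability <- function(studyArea, nUsed, ratio = 20, seed = NULL) {
  stopIfNot(ratio >= 1, "ratio must be >= 1")
  stopIfNot(nUsed >= 1, "need at least one used point")
  n <- as.integer(ratio * nUsed)
  withSeed(seed, data.frame(
    x_km = runif(n, studyArea[1], studyArea[2]),
    y_km = runif(n, studyArea[3], studyArea[4])))
}

#' Assemble a used-available table with covariates
#'
#' Used rows are in-window migration fixes; available rows are uniform
#' draws over the study area (20 per used point by default).  Points on
#' nodata covariate cells are dropped with a message.
#'
#' @param tracks list of [TelemetryTrack-class].
#' @param windows list of [MigrationWindow-class] (same order; `NULL`
#'   entries skipped).
#' @param stack a [CovariateStack-class].
#' @param studyArea availability rectangle; default the stack extent.
#' @param ratio available:used ratio.
#' @param seed RNG seed for the availability draw.
#' @return data.frame with `response` (1 used / 0 available), `animal_id`,
#'   `year`, coordinates and covariates.
#' @export
buildUsedAvailable <- function(tracks, windows, stack, studyArea = NULL,
                               ratio = 20, seed = NULL) {
  if (is.null(studyArea)) studyArea <- gridExtent(stack@ruggedness_z)
  used <- list()
  for (i in seq_along(tracks)) {
    win <- windows[[i]]
    if (is.null(win)) next
    fx <- tracks[[i]]@fixes[win@startIndex:win@endIndex, ]
    used[[length(used) + 1L]] <- data.frame(
      animal_id = tracks[[i]]@animalId, year = tracks[[i]]@year,
      x_km = fx$x_km, y_km = fx$y_km)
  }
  stopIfNot(length(used) > 0, "no used points (no migrations detected)")
  used <- do.call(rbind, used)
  avail <- sampleAvailability(studyArea, nrow(used), ratio, seed)
  # available points inherit animal/year labels cyclically so mixed models
  # can include them in the grouping structure
  idx <- rep(seq_len(nrow(used)), length.out = nrow(avail))
  tab <- rbind(
    data.frame(response = 1, animal_id = used$animal_id, year = used$year,
               x_km = used$x_km, y_km = used$y_km),
    data.frame(response = 0, animal_id = used$animal_id[idx],
               year = used$year[idx], x_km = avail$x_km, y_km = avail$y_km))
  cov <- extractCovariates(stack, tab$x_km, tab$y_km)
  out <- cbind(tab, cov)
  ok <- complete.cases(out)
  if (any(!ok)) message(sprintf("dropping %d points on nodata cells",
                                sum(!ok)))
  out[ok, ]
}

rsfTerms <- function(groups) {
  terms <- c(ruggedness = "ruggedness_z", river = "river",
             roads = "road_decay", landcover = "landcover")
  unname(terms[groups])
}

#' Factorial candidate model set
#'
#' All subsets of the covariate groups (land cover enters as a single group
#' of three indicator contrasts against the open reference), including the
#' intercept-only model: `2^4 = 16` formulas for the four standard groups.
#'
#' @param groups character vector of group names among `"ruggedness"`,
#'   `"river"`, `"roads"`, `"landcover"`.
#' @return named list of model formulas (names list the included groups).
#' @export
candidateModelSet <- function(groups = c("ruggedness", "river", "roads",
                                         "landcover")) {
  stopIfNot(length(groups) >= 1, "need at least one covariate group")
  out <- list(`intercept_only` = response ~ 1)
  for (sz in seq_along(groups)) {
    combos <- utils::combn(groups, sz, simplify = FALSE)
    for (cc in combos) {
      rhs <- paste(rsfTerms(cc), collapse = " + ")
      out[[paste(cc, collapse = "+")]] <-
        as.formula(paste("response ~", rhs))
    }
  }
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing each design column on the
#' others; a perfectly collinear column is reported as `Inf`.
#'
#' @param X numeric matrix or data.frame of design columns (>= 2 columns,
#'   none constant).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  stopIfNot(ncol(X) >= 2, "need at least 2 columns")
  stopIfNot(all(apply(X, 2, stats::sd) > 0), "constant column in design")
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> setNames(colnames(X))
}

#' Fit a used-available resource selection model
#'
#' Binomial logistic regression of used (1) versus available (0) points.
#' With `randomEffects = TRUE`, random intercepts for year nested within
#' animal are added and the model is fit by Laplace-approximate maximum
#' likelihood (`lme4::glmer`); when the random-intercept variances collapse
#' to the boundary this reduces to the fixed-effects fit.  Land cover uses
#' the open class as reference.
#'
#' @param table a used-available data.frame (see [buildUsedAvailable()]).
#' @param formula model formula on `response` (see [candidateModelSet()]).
#' @param randomEffects logical.
#' @param label optional model label.
#' @return an [RSFFit-class].
#' @export
fitRSF <- function(table, formula = response ~ ruggedness_z + river +
                     road_decay + landcover,
                   randomEffects = FALSE, label = NULL) {
  stopIfNot(length(unique(table$response)) == 2,
            "response must contain both used and available rows")
  if (is.null(label)) label <- paste(deparse(formula), collapse = "")
  n <- nrow(table)
  if (randomEffects) {
    ref <- stats::update(formula, . ~ . + (1 | animal_id / year))
    fit <- suppressMessages(lme4::glmer(ref, data = table, family = binomial))
    cf <- lme4::fixef(fit)
    vc <- as.matrix(vcov(fit))
    ll <- as.numeric(logLik(fit))
    k <- length(cf) + 2   # two random-intercept variances
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
    rv <- vapply(lme4::VarCorr(fit), function(m) m[1, 1], numeric(1))
  } else {
    fit <- glm(formula, data = table, family = binomial)
    if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
    p <- fit$fitted.values
    if (any(p > 1 - 1e-10) && any(p < 1e-10) &&
        max(abs(coef(fit)), na.rm = TRUE) > 15)
      stop("complete separation: fitted probabilities at 0/1", call. = FALSE)
    if (anyNA(coef(fit)))
      stop("rank-deficient design (aliased covariate)", call. = FALSE)
    cf <- coef(fit)
    vc <- as.matrix(vcov(fit))
    ll <- as.numeric(logLik(fit))
    k <- length(cf)
    conv <- TRUE
    rv <- setNames(numeric(0), character(0))
  }
  se <- sqrt(diag(vc))
  new("RSFFit", coefficients = cf, se = se, vcov = vc, logLik = ll,
      n = n, k = k, aicc = if (conv) aicc(ll, k, n) else NA_real_,
      converged = conv, randomEffects = randomEffects, ranefVar = rv,
      label = label)
}

akaikeWeights <- function(aiccs) {
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Select the road distance-decay parameter by AICc
#'
#' Fits one univariate logistic model per candidate decay range `alpha`
#' (`response ~ exp(-alpha/d)`) plus one linear distance model
#' (`response ~ d`), ranks all candidates by AICc and returns Akaike
#' weights.  The default candidate grid is every km from 1-20, every 5 km
#' from 25-50, every 10 km from 60-100 and every 50 km from 150-350 (36
#' values).
#'
#' @param table used-available data.frame with a `road_dist_km` column.
#' @param candidates numeric vector of candidate alphas (km).
#' @param randomEffects logical, passed to [fitRSF()].
#' @return data.frame sorted by AICc with columns `label`, `alpha` (`NA`
#'   for the linear model), `aicc`, `delta_aicc`, `weight`.
#' @export
selectDecayAlpha <- function(table,
                             candidates = defaultAlphaGrid(),
                             randomEffects = FALSE) {
  stopIfNot(length(candidates) >= 1, "need at least one candidate alpha")
  labs <- c(sprintf("alpha_%g", candidates), "linear_distance")
  fits <- vector("list", length(labs))
  aiccs <- rep(NA_real_, length(labs))
  d <- table$road_dist_km
  for (i in seq_along(candidates)) {
    tb <- table
    tb$road_decay <- ifelse(d <= 0, 0, exp(-candidates[i] / d))
    f <- tryCatch(fitRSF(tb, response ~ road_decay, randomEffects,
                         label = labs[i]),
                  error = function(e) {
                    warning(sprintf("candidate %s dropped: %s", labs[i],
                                    conditionMessage(e)))
                    NULL
                  })
    fits[[i]] <- f
    if (!is.null(f)) aiccs[i] <- f@aicc
  }
  flin <- tryCatch(fitRSF(table, response ~ road_dist_km, randomEffects,
                          label = "linear_distance"),
                   error = function(e) {
                     warning("linear distance candidate dropped: ",
                             conditionMessage(e))
                     NULL
                   })
  if (!is.null(flin)) aiccs[length(labs)] <- flin@aicc
  ok <- is.finite(aiccs)
  res <- data.frame(label = labs[ok],
                    alpha = c(candidates, NA_real_)[ok],
                    aicc = aiccs[ok])
  res <- res[order(res$aicc), ]
  res$delta_aicc <- res$aicc - res$aicc[1]
  res$weight <- akaikeWeights(res$aicc)
  rownames(res) <- NULL
  res
}

#' Candidate alpha grid for the decay scan
#' @return the 36-value grid: 1-20 km by 1, 25-50 by 5, 60-100 by 10,
#'   150-350 by 50.
#' @export
defaultAlphaGrid <- function() {
  c(1:20, seq(25, 50, 5), seq(60, 100, 10), seq(150, 350, 50))
}

#' Rank the factorial candidate set by AICc
#'
#' @param table used-available data.frame.
#' @param formulas named list from [candidateModelSet()].
#' @param randomEffects logical.
#' @return list with `table` (label, aicc, delta_aicc, weight, sorted) and
#'   `fits` (named list of [RSFFit-class]).
#' @export
selectRSFModel <- function(table, formulas = candidateModelSet(),
                           randomEffects = FALSE) {
  fits <- lapply(names(formulas), function(nm)
    tryCatch(fitRSF(table, formulas[[nm]], randomEffects, label = nm),
             error = function(e) {
               warning(sprintf("model %s dropped: %s", nm,
                               conditionMessage(e)))
               NULL
             }))
  names(fits) <- names(formulas)
  ok <- !vapply(fits, is.null, logical(1))
  aiccs <- vapply(fits[ok], function(f) f@aicc, numeric(1))
  tab <- data.frame(label = names(aiccs), aicc = aiccs)
  tab <- tab[order(tab$aicc), ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  tab$weight <- akaikeWeights(tab$aicc)
  rownames(tab) <- NULL
  list(table = tab, fits = fits[ok])
}

# Fixed-effect linear predictor over the stack, excluding the intercept.
stackLinearPredictor <- function(fit, stack) {
  cf <- fit@coefficients
  d <- dim(stack@ruggedness_z@values)
  lp <- matrix(0, d[1], d[2])
  addTerm <- function(lp, name, layer) {
    if (name %in% names(cf)) lp + cf[[name]] * layer else lp
  }
  lp <- addTerm(lp, "ruggedness_z", stack@ruggedness_z@values)
  lp <- addTerm(lp, "river", stack@river@values)
  lp <- addTerm(lp, "road_decay", stack@road_decay@values)
  lp <- addTerm(lp, "road_dist_km", stack@road_dist_km@values)
  lc <- stack@landcover@values
  for (cls in c(dense = 1, burned = 2, coastal = 3)) {
    nm <- paste0("landcover", names(which(c(dense = 1, burned = 2,
                                            coastal = 3) == cls)))
    if (nm %in% names(cf)) lp <- lp + cf[[nm]] * (lc == cls)
  }
  # any nodata covariate propagates
  mask <- is.finite(stack@ruggedness_z@values) &
    is.finite(stack@river@values) & is.finite(lc) &
    is.finite(stack@road_decay@values)
  lp[!mask] <- NA_real_
  lp
}

#' Predict relative habitat suitability over the study area
#'
#' Exponentiates the fixed-effect linear predictor (no intercept, no random
#' effects) cell by cell and max-normalizes, giving relative suitability
#' `hs` in `(0, 1]` with the best cell exactly 1.
#'
#' @param fit a converged [RSFFit-class].
#' @param stack a [CovariateStack-class].
#' @return `RasterGrid` of `hs`.
#' @export
predictSuitability <- function(fit, stack) {
  stopIfNot(fit@converged, "fit did not converge")
  lp <- stackLinearPredictor(fit, stack)
  w <- exp(lp)
  mx <- max(w[is.finite(w)])
  stopIfNot(is.finite(mx) && mx > 0, "no finite suitability values")
  out <- stack@ruggedness_z
  out@values <- w / mx
  out
}

#' k-fold cross-validation of an RSF by binned area-adjusted frequencies
#'
#' Used points are split into `k` folds; each fold's model is trained on
#' the remaining used points plus all available points, withheld used
#' points are scored, scores are cut into equal-interval bins spanning the
#' available-point score range, and the Spearman rank correlation between
#' bin rank and area-adjusted use frequency (used count / available count
#' per bin, normalized) is averaged over folds.
#'
#' @param table used-available data.frame.
#' @param formula RSF formula.
#' @param k number of folds (>= 2).
#' @param bins number of equal-interval score bins.
#' @param seed RNG seed for the fold assignment.
#' @param randomEffects logical.
#' @return list with `mean_rho` and per-fold `rho`.
#' @export
kfoldValidate <- function(table, formula = response ~ ruggedness_z + river +
                            road_decay + landcover,
                          k = 10, bins = 10, seed = NULL,
                          randomEffects = FALSE) {
  stopIfNot(k >= 2, "need k >= 2 folds")
  usedIdx <- which(table$response == 1)
  stopIfNot(length(usedIdx) >= k, "need at least k used points")
  fold <- withSeed(seed, sample(rep(seq_len(k), length.out = length(usedIdx))))
  rhos <- numeric(k)
  for (f in seq_len(k)) {
    test <- usedIdx[fold == f]
    train <- table[-test, ]
    fit <- fitRSF(train, formula, randomEffects)
    score <- function(df) {
      lp <- rep(0, nrow(df))
      cf <- fit@coefficients
      for (nm in names(cf)) {
        if (nm == "(Intercept)") next
        if (nm %in% names(df)) lp <- lp + cf[[nm]] * df[[nm]]
        else if (startsWith(nm, "landcover"))
          lp <- lp + cf[[nm]] * (df$landcover == sub("landcover", "", nm))
      }
      exp(lp)
    }
    sAvail <- score(table[table$response == 0, ])
    sTest <- score(table[test, ])
    brks <- seq(min(sAvail), max(sAvail), length.out = bins + 1)
    brks[1] <- -Inf; brks[length(brks)] <- Inf
    bAvail <- table(cut(sAvail, brks))
    bTest <- table(cut(sTest, brks))
    ok <- bAvail > 0
    if (any(!ok)) warning("empty availability bins excluded from correlation")
    freq <- as.numeric(bTest[ok]) / as.numeric(bAvail[ok])
    freq <- freq / sum(freq)
    rhos[f] <- cor(seq_along(freq), freq, method = "spearman")
  }
  list(mean_rho = mean(rhos), rho = rhos)
}

#' Bootstrap response curve for the road covariate
#'
#' Draws coefficient vectors from the multivariate normal sampling
#' distribution of the fitted fixed effects and evaluates relative
#' selection over a grid of road distances with the remaining covariates
#' held at their mean (ruggedness) or baseline (river 0, open land cover),
#' returning the pointwise mean and 95% interval.
#'
#' @param fit a converged [RSFFit-class] containing a `road_decay` term.
#' @param alpha decay parameter (km) used to map distance to the covariate.
#' @param distGrid distances (km) at which to evaluate.
#' @param nBoot bootstrap draws (default 500).
#' @param seed RNG seed.
#' @param meanRuggedness value at which ruggedness is held (default 0, the
#'   standardized mean).
#' @return data.frame with `dist_km`, `mean`, `lo`, `hi`.
#' @export
bootstrapResponse <- function(fit, alpha, distGrid = seq(0.5, 100, by = 0.5),
                              nBoot = 500, seed = NULL,
                              meanRuggedness = 0) {
  stopIfNot(fit@converged, "fit did not converge")
  cf <- fit@coefficients
  stopIfNot("road_decay" %in% names(cf), "fit has no road_decay term")
  vc <- fit@vcov
  ev <- eigen(vc, symmetric = TRUE, only.values = TRUE)$values
  stopIfNot(min(ev) >= -1e-8 * max(abs(ev), 1),
            "coefficient covariance is not positive semi-definite")
  draws <- if (all(abs(vc) < 1e-300)) {
    matrix(rep(cf, each = nBoot), nBoot, length(cf),
           dimnames = list(NULL, names(cf)))
  } else {
    withSeed(seed, MASS::mvrnorm(nBoot, mu = cf, Sigma = vc))
  }
  colnames(draws) <- names(cf)
  decay <- ifelse(distGrid <= 0, 0, exp(-alpha / distGrid))
  lpOf <- function(b) {
    lp <- rep(0, length(decay))
    if ("ruggedness_z" %in% names(cf))
      lp <- lp + b[["ruggedness_z"]] * meanRuggedness
    lp + b[["road_decay"]] * decay   # river = 0, land cover = open
  }
  curves <- apply(draws, 1, function(b) exp(lpOf(b)))
  data.frame(dist_km = distGrid,
             mean = rowMeans(curves),
             lo = apply(curves, 1, quantile, 0.025),
             hi = apply(curves, 1, quantile, 0.975))
}
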