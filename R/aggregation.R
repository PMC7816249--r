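# Scenario ranking by summed current at observed fixes, support tabulation,
# and population-level connectivity maps with individual-fold validation.

#' Summed current at observed fixes
#'
#' Sums the current-density value of the cell containing each fix (one
#' contribution per fix, so revisited cells count once per fix).  Fixes on
#' nodata cells contribute 0 and are counted in the `nodata_fixes`
#' attribute.
#'
#' @param current `RasterGrid` current-density map.
#' @param fixes data.frame (or matrix) with `x_km`, `y_km`.
#' @return scalar summed current.
#' @export
scoreScenario <- function(current, fixes) {
  if (!nrow(fixes)) return(structure(0, nodata_fixes = 0L))
  v <- valuesAtXY(current, fixes$x_km, fixes$y_km)
  nbad <- sum(is.na(v))
  if (nbad) message(sprintf("%d fixes on nodata cells contribute 0", nbad))
  structure(sum(v, na.rm = TRUE), nodata_fixes = as.integer(nbad))
}

# fixed tie-break order: simpler scenarios preferred on exact score ties
scenarioTieOrder <- c(r0 = 1, r3 = 2, r1 = 3, r4 = 4, r2 = 5)

#' Rank the five resistance scenarios for one individual
#'
#' @param maps named list of five current-density `RasterGrid`s (names
#'   `r0`..`r4`).
#' @param fixes the individual's in-window fixes (`x_km`, `y_km`).
#' @param id individual label (animal-season-year).
#' @return list with `id`, `scores` (named, descending), `top` scenario id
#'   and a `tie` flag (exact score tie on the top rank, broken by the fixed
#'   order r0 < r3 < r1 < r4 < r2).
#' @export
rankIndividual <- function(maps, fixes, id = "") {
  need <- names(resistanceScenarios())
  missing <- setdiff(need, names(maps))
  stopIfNot(length(missing) == 0,
            paste("missing scenario map(s):", paste(missing, collapse = ", ")))
  scores <- vapply(need, function(s) as.numeric(scoreScenario(maps[[s]], fixes)),
                   numeric(1))
  ord <- order(-scores, scenarioTieOrder[need])
  tie <- sum(scores == max(scores)) > 1
  list(id = id, scores = scores[ord], top = need[ord][1], tie = tie)
}

#' Tabulate top-ranked scenario support across individuals
#'
#' @param rankings list of [rankIndividual()] results.
#' @return data.frame with `scenario`, `count`, `proportion` (sums to 1).
#' @export
tabulateSupport <- function(rankings) {
  stopIfNot(length(rankings) >= 1, "need at least one ranking")
  tops <- vapply(rankings, function(r) r$top, character(1))
  sc <- names(resistanceScenarios())
  counts <- vapply(sc, function(s) sum(tops == s), numeric(1))
  data.frame(scenario = sc, count = counts,
             proportion = counts / sum(counts), row.names = NULL)
}

#' Population-level connectivity map
#'
#' Each individual's top-scenario current map is standardized to sum to one
#' over valid cells, then the standardized maps are summed, so the output
#' sums to the number of individuals.
#'
#' @param maps list of per-individual current-density `RasterGrid`s (each
#'   individual's top-ranked scenario map).
#' @param season season label.
#' @param roadsVariant `"baseline"` or `"with_proposed"`.
#' @return a [PopulationMap-class].
#' @export
populationMap <- function(maps, season = "fall", roadsVariant = "baseline") {
  stopIfNot(length(maps) >= 1, "need at least one individual map")
  acc <- NULL
  for (m in maps) {
    v <- m@values
    s <- sum(v[is.finite(v)])
    stopIfNot(is.finite(s) && s > 0, "individual map with zero total current")
    v[is.finite(v)] <- v[is.finite(v)] / s
    acc <- if (is.null(acc)) v else {
      both <- is.finite(acc) & is.finite(v)
      out <- acc
      out[both] <- acc[both] + v[both]
      out[is.finite(v) & !is.finite(acc)] <- v[is.finite(v) & !is.finite(acc)]
      out
    }
  }
  g <- maps[[1]]
  g@values <- acc
  # renormalize exact: summation must equal n within 1e-9
  tot <- sum(acc[is.finite(acc)])
  g@values[is.finite(acc)] <- acc[is.finite(acc)] * (length(maps) / tot)
  new("PopulationMap", raster = g, season = season,
      nIndividuals = length(maps), roadsVariant = roadsVariant)
}

#' Validate a population connectivity map by individual k-fold
#'
#' Folds split individuals (not fixes) to avoid leakage.  Per fold the
#' population map is rebuilt from training individuals and the withheld
#' individuals' fixes are scored by the binned-rank procedure used for RSF
#' validation: map values are cut into equal-interval bins over valid
#' cells, the area-adjusted frequency of withheld fixes per bin (fix count
#' / cell count, normalized) is correlated (Spearman) with bin rank.  Also
#' reports the mean map value at all fixes versus over the study area.
#'
#' Current-density maps are extremely right-skewed (terminal cells carry
#' the injection value), so bins are quantile-based by default: equal
#' interval bins would put nearly every cell in the lowest bin.
#'
#' @param maps per-individual top-scenario current maps.
#' @param fixesByIndividual list of fix data.frames, same order as `maps`.
#' @param k number of folds (reduced with a warning when individuals are
#'   fewer).
#' @param bins number of bins.
#' @param binMethod `"quantile"` (equal-area, default) or `"interval"`.
#' @param seed fold-assignment seed.
#' @param season,roadsVariant labels for the rebuilt maps.
#' @return list with `mean_rho`, `rho` per fold, `mean_at_fixes`,
#'   `mean_study_area`.
#' @export
validatePopulationMap <- function(maps, fixesByIndividual, k = 10, bins = 10,
                                  seed = NULL, season = "fall",
                                  roadsVariant = "baseline",
                                  binMethod = c("quantile", "interval")) {
  binMethod <- match.arg(binMethod)
  n <- length(maps)
  stopIfNot(n == length(fixesByIndividual), "maps and fixes must align")
  stopIfNot(n >= 2, "need at least two individuals")
  if (n < k) {
    warning(sprintf("only %d individuals: reducing k from %d", n, k))
    k <- n
  }
  fold <- withSeed(seed, sample(rep(seq_len(k), length.out = n)))
  rhos <- numeric(k)
  for (f in seq_len(k)) {
    train <- which(fold != f); test <- which(fold == f)
    pm <- populationMap(maps[train], season, roadsVariant)
    v <- pm@raster@values
    fin <- v[is.finite(v)]
    brks <- if (binMethod == "interval")
      seq(min(fin), max(fin), length.out = bins + 1) else
      unique(quantile(fin, seq(0, 1, length.out = bins + 1)))
    if (length(brks) < 3) {       # constant map: rank correlation undefined
      warning("map values too uniform to bin; fold rho undefined")
      rhos[f] <- NA_real_
      next
    }
    brks[1] <- -Inf; brks[length(brks)] <- Inf
    area <- table(cut(fin, brks))
    fx <- do.call(rbind, fixesByIndividual[test])
    fv <- valuesAtXY(pm@raster, fx$x_km, fx$y_km)
    fv <- fv[!is.na(fv)]
    use <- table(cut(fv, brks))
    ok <- area > 0
    if (any(!ok)) warning("empty bins excluded from correlation")
    freq <- as.numeric(use[ok]) / as.numeric(area[ok])
    freq <- freq / sum(freq)
    rhos[f] <- cor(seq_along(freq), freq, method = "spearman")
  }
  full <- populationMap(maps, season, roadsVariant)
  allfx <- do.call(rbind, fixesByIndividual)
  atfix <- valuesAtXY(full@raster, allfx$x_km, allfx$y_km)
  v <- full@raster@values
  list(mean_rho = mean(rhos, na.rm = TRUE), rho = rhos,
       mean_at_fixes = mean(atfix, na.rm = TRUE),
       mean_study_area = mean(v[is.finite(v)]))
}
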