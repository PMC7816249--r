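# Suitability-to-resistance scenario transforms and the 1-1,000 stretch.
#
# Five hypotheses link relative habitat suitability hs (0, 1] to landscape
# resistance r: neutral (r = 1), positive linear (r = hs), negative
# exponential (r = (1/hs)^2), negative linear (r = 1/hs) and negative
# logarithmic (r = ln(1/hs)).  All but the neutral surface are linearly
# stretched to [1, 1000]; only relative resistance magnitudes matter to the
# circuit stage.

#' Scenario identifiers and labels
#' @return named character vector mapping id to descriptive label.
#' @export
resistanceScenarios <- function() {
  c(r0 = "neutral", r1 = "positive linear", r2 = "negative exponential",
    r3 = "negative linear", r4 = "negative logarithmic")
}

scenarioFun <- function(id) {
  switch(id,
         r0 = function(hs) rep(1, length(hs)),
         r1 = function(hs) hs,
         r2 = function(hs) (1 / hs)^2,
         r3 = function(hs) 1 / hs,
         r4 = function(hs) log(1 / hs),
         stop("unknown scenario: ", id, call. = FALSE))
}

#' Apply a suitability-to-resistance scenario transform
#'
#' @param hs `RasterGrid` of relative habitat suitability in `(0, 1]`.
#' @param scenario one of `"r0"`..`"r4"`.
#' @param clampEpsilon suitability values below this are clamped up before
#'   division or log (must lie in `(0, 0.1)`); the subsequent stretch makes
#'   results insensitive to the exact value.
#' @return raw (unstretched) resistance `RasterGrid`; nodata propagated.
#' @export
applyScenario <- function(hs, scenario, clampEpsilon = 1e-3) {
  stopIfNot(scenario %in% names(resistanceScenarios()),
            "scenario must be one of r0..r4")
  stopIfNot(clampEpsilon > 0 && clampEpsilon < 0.1,
            "clampEpsilon must lie in (0, 0.1)")
  v <- hs@values
  fin <- is.finite(v)
  stopIfNot(all(v[fin] <= 1 + 1e-9),
            "hs > 1: suitability must be max-normalized to (0, 1]")
  stopIfNot(all(v[fin] > 0), "hs must be strictly positive")
  v[fin] <- pmin(pmax(v[fin], clampEpsilon), 1)
  f <- scenarioFun(scenario)
  out <- hs
  w <- v
  w[fin] <- f(v[fin])
  w[!fin] <- NA_real_
  out@values <- w
  out
}

#' Linearly stretch a raw resistance surface to a fixed range
#'
#' `r' = lo + (hi - lo) (r - min) / (max - min)` over valid cells; a
#' constant surface maps to `lo`.  Rank order is preserved.
#'
#' @param raw raw resistance `RasterGrid`.
#' @param lo,hi stretch bounds (defaults 1 and 1000).
#' @return stretched `RasterGrid`.
#' @export
stretchResistance <- function(raw, lo = 1, hi = 1000) {
  v <- raw@values
  fin <- is.finite(v)
  stopIfNot(any(fin), "no valid cells to stretch")
  mn <- min(v[fin]); mx <- max(v[fin])
  if (mx == mn) v[fin] <- lo else {
    s <- lo + (hi - lo) * (v[fin] - mn) / (mx - mn)
    # pin the extremes exactly; rounding may otherwise overshoot by one ulp
    s <- pmin(pmax(s, lo), hi)
    s[v[fin] == mn] <- lo
    s[v[fin] == mx] <- hi
    v[fin] <- s
  }
  out <- raw
  out@values <- v
  out
}

#' Build a resistance surface for one scenario
#'
#' Applies the transform and (except for the neutral scenario) the
#' 1-1,000 stretch.
#'
#' @inheritParams applyScenario
#' @param lo,hi stretch bounds.
#' @param hsSource provenance tag recorded on the surface.
#' @return a [ResistanceSurface-class].
#' @export
buildResistance <- function(hs, scenario, clampEpsilon = 1e-3, lo = 1,
                            hi = 1000, hsSource = "") {
  raw <- applyScenario(hs, scenario, clampEpsilon)
  rast <- if (scenario == "r0") raw else stretchResistance(raw, lo, hi)
  new("ResistanceSurface", raster = rast, scenario = scenario,
      stretched = scenario != "r0", clampEpsilon = clampEpsilon,
      hsSource = hsSource)
}

#' Rebuild a resistance surface with proposed roads injected
#'
#' Recomputes the road decay covariate from the union of existing and
#' proposed roads, re-predicts suitability with the unchanged season
#' coefficients and decay parameter, re-applies the scenario transform and
#' re-stretches.  With an empty proposed set the result is bitwise
#' identical to the baseline surface.
#'
#' @param fit the season's [RSFFit-class] (coefficients unchanged).
#' @param bundle the [LandscapeBundle-class] carrying both road sets.
#' @param alpha the season's selected decay parameter (km).
#' @param grain analysis grain (km).
#' @param scenario the individual's top-ranked scenario id.
#' @param clampEpsilon,lo,hi as in [buildResistance()].
#' @return list with `surface` ([ResistanceSurface-class]), `hs` and the
#'   rebuilt `stack`.
#' @export
rebuildWithRoads <- function(fit, bundle, alpha, grain = 1, scenario = "r3",
                             clampEpsilon = 1e-3, lo = 1, hi = 1000) {
  stack <- buildCovariateStack(bundle, alpha, grain,
                               includeProposed = length(bundle@roadsProposed) > 0)
  hs <- predictSuitability(fit, stack)
  list(surface = buildResistance(hs, scenario, clampEpsilon, lo, hi,
                                 hsSource = "with_proposed_roads"),
       hs = hs, stack = stack)
}
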