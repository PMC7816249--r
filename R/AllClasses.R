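#' RasterGrid: a georeferenced numeric surface
#'
#' Minimal in-memory raster: a numeric matrix plus an origin, a square cell
#' size and an opaque CRS tag.  Row 1 is the top (northernmost) row and
#' column 1 the west; coordinates refer to cell centres.  `NA` cells are
#' nodata.  All covariate, suitability, resistance and current-density
#' surfaces in the package are `RasterGrid`s sharing one geometry.
#'
#' @slot values numeric matrix; `NA` = nodata.
#' @slot xmin,ymin numeric, coordinates (km) of the lower-left raster corner.
#' @slot cellSize numeric, cell edge length in km (> 0).
#' @slot crs character tag carried opaquely (no reprojection is done).
#' @exportClass RasterGrid
setClass("RasterGrid",
  representation(values = "matrix", xmin = "numeric", ymin = "numeric",
                 cellSize = "numeric", crs = "character"),
  prototype(values = matrix(numeric(0), 0, 0), xmin = 0, ymin = 0,
            cellSize = 1, crs = ""))

setValidity("RasterGrid", function(object) {
  msgs <- character(0)
  if (!is.numeric(object@values)) msgs <- c(msgs, "values must be numeric")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (length(object@xmin) != 1L || length(object@ymin) != 1L)
    msgs <- c(msgs, "xmin/ymin must be scalars")
  if (length(msgs)) msgs else TRUE
})

#' TelemetryTrack: ordered GPS fixes for one animal-season-year
#'
#' @slot animalId character label of the collared animal.
#' @slot season `"fall"` or `"spring"`.
#' @slot year integer year of the migration.
#' @slot fixes data.frame with columns `timestamp` (POSIXct), `x_km`, `y_km`;
#'   timestamps strictly increasing, at least 3 fixes.
#' @exportClass TelemetryTrack
setClass("TelemetryTrack",
  representation(animalId = "character", season = "character",
                 year = "integer", fixes = "data.frame"))

setValidity("TelemetryTrack", function(object) {
  f <- object@fixes
  msgs <- character(0)
  if (!all(c("timestamp", "x_km", "y_km") %in% names(f)))
    msgs <- c(msgs, "fixes must have timestamp, x_km, y_km")
  else {
    if (nrow(f) < 3L) msgs <- c(msgs, "track needs at least 3 fixes")
    if (nrow(f) > 1L && any(diff(as.numeric(f$timestamp)) <= 0))
      msgs <- c(msgs, "timestamps must be strictly increasing")
  }
  if (!object@season %in% c("fall", "spring"))
    msgs <- c(msgs, "season must be 'fall' or 'spring'")
  if (length(msgs)) msgs else TRUE
})

#' LandscapeBundle: co-registered landscape layers and vector features
#'
#' @slot elevation,landcover `RasterGrid`s on a shared geometry; landcover
#'   classes are 0 = open (reference), 1 = dense vegetation, 2 = burned,
#'   3 = coastal water.
#' @slot rivers,roadsExisting,roadsProposed lists of polylines, each a
#'   two-column matrix of vertex coordinates (km).
#' @slot communities data.frame with `name`, `x_km`, `y_km`.
#' @slot extent numeric `c(xmin, xmax, ymin, ymax)` (km).
#' @slot cellSize numeric (km).
#' @exportClass LandscapeBundle
setClass("LandscapeBundle",
  representation(elevation = "RasterGrid", landcover = "RasterGrid",
                 rivers = "list", roadsExisting = "list",
                 roadsProposed = "list", communities = "data.frame",
                 extent = "numeric", cellSize = "numeric"))

setValidity("LandscapeBundle", function(object) {
  msgs <- character(0)
  if (!identical(dim(object@elevation@values), dim(object@landcover@values)))
    msgs <- c(msgs, "elevation and landcover must share shape")
  lc <- object@landcover@values
  if (!all(lc[is.finite(lc)] %in% 0:3))
    msgs <- c(msgs, "landcover classes must be in {0,1,2,3}")
  if (object@cellSize <= 0) msgs <- c(msgs, "cellSize must be > 0")
  if (length(object@extent) != 4L) msgs <- c(msgs, "extent must be length 4")
  if (length(msgs)) msgs else TRUE
})

#' CovariateStack: the four analysis-grain RSF covariate layers
#'
#' @slot ruggedness_z standardized vector ruggedness (mean 0, sd 1).
#' @slot river 0/1 major-river indicator.
#' @slot landcover integer classes 0-3, 0 = open reference.
#' @slot road_decay exp(-alpha/d) road proximity covariate in [0, 1).
#' @slot road_dist_km raw Euclidean distance to the nearest road (km), kept
#'   so the linear-distance candidate model can be fit.
#' @slot alpha decay range parameter (km).
#' @slot grain analysis cell size (km).
#' @exportClass CovariateStack
setClass("CovariateStack",
  representation(ruggedness_z = "RasterGrid", river = "RasterGrid",
                 landcover = "RasterGrid", road_decay = "RasterGrid",
                 road_dist_km = "RasterGrid", alpha = "numeric",
                 grain = "numeric"))

setValidity("CovariateStack", function(object) {
  msgs <- character(0)
  dims <- lapply(list(object@ruggedness_z, object@river, object@landcover,
                      object@road_decay, object@road_dist_km),
                 function(g) dim(g@values))
  if (length(unique(dims)) != 1L)
    msgs <- c(msgs, "all layers must be co-registered")
  rd <- object@road_decay@values
  if (any(rd[is.finite(rd)] < 0 | rd[is.finite(rd)] >= 1))
    msgs <- c(msgs, "road_decay must lie in [0, 1)")
  z <- object@ruggedness_z@values[is.finite(object@ruggedness_z@values)]
  # constant (e.g. flat-terrain) layers standardize to all zero
  if (length(z) > 1L && stats::sd(z) > 0 &&
      (abs(mean(z)) > 1e-6 || abs(stats::sd(z) - 1) > 1e-6))
    msgs <- c(msgs, "ruggedness_z must be standardized (mean 0, sd 1)")
  if (object@alpha <= 0) msgs <- c(msgs, "alpha must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' MigrationWindow: NSD-delimited migration bout
#'
#' @slot startIndex,endIndex fix indices bounding the migration.
#' @slot startPoint,endPoint coordinates (km) of the bounding fixes.
#' @slot nsd numeric vector of net-squared displacement (km^2) per fix.
#' @exportClass MigrationWindow
setClass("MigrationWindow",
  representation(startIndex = "integer", endIndex = "integer",
                 startPoint = "numeric", endPoint = "numeric",
                 nsd = "numeric"))

setValidity("MigrationWindow", function(object) {
  msgs <- character(0)
  if (!(object@startIndex >= 1L && object@startIndex < object@endIndex &&
        object@endIndex <= length(object@nsd)))
    msgs <- c(msgs, "need 1 <= startIndex < endIndex <= n_fixes")
  if (length(object@nsd) && abs(object@nsd[1]) > 1e-12)
    msgs <- c(msgs, "nsd[1] must be 0")
  if (length(msgs)) msgs else TRUE
})

#' RSFFit: a fitted used-available resource selection model
#'
#' @slot coefficients,se named numeric vectors of fixed effects.
#' @slot vcov fixed-effect covariance matrix.
#' @slot logLik,n,k,aicc scalars; `aicc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#' @slot converged logical.
#' @slot randomEffects logical: random intercepts (year within animal) used.
#' @slot ranefVar named numeric vector of random-intercept variances.
#' @slot label model label (covariate groups included).
#' @exportClass RSFFit
setClass("RSFFit",
  representation(coefficients = "numeric", se = "numeric", vcov = "matrix",
                 logLik = "numeric", n = "numeric", k = "numeric",
                 aicc = "numeric", converged = "logical",
                 randomEffects = "logical", ranefVar = "numeric",
                 label = "character"))

setValidity("RSFFit", function(object) {
  msgs <- character(0)
  if (object@k < 1) msgs <- c(msgs, "k must be >= 1")
  if (object@n <= object@k + 1) msgs <- c(msgs, "need n > k + 1")
  if (object@converged && is.finite(object@aicc)) {
    expect <- -2 * object@logLik + 2 * object@k +
      2 * object@k * (object@k + 1) / (object@n - object@k - 1)
    if (abs(expect - object@aicc) > 1e-6 * max(1, abs(expect)))
      msgs <- c(msgs, "aicc inconsistent with logLik, k, n")
  }
  if (length(msgs)) msgs else TRUE
})

#' ResistanceSurface: a suitability-to-resistance scenario realisation
#'
#' @slot raster resistance `RasterGrid` (dimensionless).
#' @slot scenario one of `"r0"`, `"r1"`, `"r2"`, `"r3"`, `"r4"`.
#' @slot stretched logical, TRUE once linearly rescaled to `[lo, hi]`.
#' @slot clampEpsilon lower clamp applied to suitability before 1/hs, log.
#' @slot hsSource provenance tag for the suitability layer.
#' @exportClass ResistanceSurface
setClass("ResistanceSurface",
  representation(raster = "RasterGrid", scenario = "character",
                 stretched = "logical", clampEpsilon = "numeric",
                 hsSource = "character"),
  prototype(hsSource = "", clampEpsilon = 1e-3, stretched = FALSE))

setValidity("ResistanceSurface", function(object) {
  msgs <- character(0)
  if (!object@scenario %in% c("r0", "r1", "r2", "r3", "r4"))
    msgs <- c(msgs, "scenario must be one of r0..r4")
  v <- object@raster@values[is.finite(object@raster@values)]
  if (object@scenario == "r0" && length(v) && any(abs(v - 1) > 1e-12))
    msgs <- c(msgs, "neutral scenario must be all 1")
  if (length(msgs)) msgs else TRUE
})

#' CircuitSolution: voltages and current densities for one terminal pair
#'
#' @slot voltages numeric vector over valid cells (ground = 0), named by
#'   cell index into the resistance matrix.
#' @slot currentMap node current-density `RasterGrid`.
#' @slot effectiveResistance source-to-ground voltage per unit injection.
#' @slot residual maximum Kirchhoff net-current violation at non-terminals.
#' @slot sourceCell,groundCell linear cell indices of the terminals.
#' @slot injection injected current (default 1).
#' @exportClass CircuitSolution
setClass("CircuitSolution",
  representation(voltages = "numeric", currentMap = "RasterGrid",
                 effectiveResistance = "numeric", residual = "numeric",
                 sourceCell = "integer", groundCell = "integer",
                 injection = "numeric"))

setValidity("CircuitSolution", function(object) {
  msgs <- character(0)
  if (object@sourceCell == object@groundCell)
    msgs <- c(msgs, "source and ground must differ")
  if (is.finite(object@effectiveResistance) &&
      object@effectiveResistance <= 0)
    msgs <- c(msgs, "effective resistance must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' PopulationMap: summed standardized per-individual current maps
#'
#' @slot raster `RasterGrid` whose valid cells sum to `nIndividuals`.
#' @slot season character.
#' @slot nIndividuals count of contributing animal-season-years.
#' @slot roadsVariant `"baseline"` or `"with_proposed"`.
#' @exportClass PopulationMap
setClass("PopulationMap",
  representation(raster = "RasterGrid", season = "character",
                 nIndividuals = "integer", roadsVariant = "character"))

setValidity("PopulationMap", function(object) {
  msgs <- character(0)
  if (!object@roadsVariant %in% c("baseline", "with_proposed"))
    msgs <- c(msgs, "roadsVariant must be baseline or with_proposed")
  s <- sum(object@raster@values[is.finite(object@raster@values)])
  if (object@nIndividuals > 0L && abs(s - object@nIndividuals) > 1e-6)
    msgs <- c(msgs, "valid cells must sum to nIndividuals")
  if (length(msgs)) msgs else TRUE
})
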