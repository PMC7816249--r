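# Covariate engineering: terrain ruggedness (vector dispersion of surface
# normals), major-river rasterization, land-cover classes, and the
# exponential road distance-decay covariate, aggregated to the analysis
# grain.

shiftMat <- function(m, dr, dc) {
  d <- dim(m)
  out <- matrix(NA_real_, d[1], d[2])
  rs <- seq_len(d[1]) + dr; cs <- seq_len(d[2]) + dc
  okr <- rs >= 1 & rs <= d[1]; okc <- cs >= 1 & cs <= d[2]
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

#' Vector ruggedness measure (VRM)
#'
#' Terrain heterogeneity as the dispersion of unit surface-normal vectors:
#' slope and aspect come from Horn 3x3 finite differences, each cell's
#' normal is `(sin s sin a, sin s cos a, cos s)` (flat cells: `(0,0,1)`),
#' components are summed over the cell and its 8 neighbours, and
#' `VRM = 1 - |R|/9` where `|R|` is the resultant magnitude.  0 = flat or
#' uniformly tilted terrain, values rise toward 1 with joint slope/aspect
#' variability.
#'
#' @param elevation `RasterGrid` of elevation in metres (cell size in km).
#' @return `RasterGrid` of VRM in `[0, 1]`; cells whose 3x3 slope kernel or
#'   ruggedness window extends past the raster edge are nodata.
#' @export
vectorRuggedness <- function(elevation) {
  e <- elevation@values
  stopIfNot(nrow(e) >= 3 && ncol(e) >= 3, "need at least a 3x3 elevation raster")
  cs_m <- elevation@cellSize * 1000
  nw <- shiftMat(e, -1, -1); n <- shiftMat(e, -1, 0); ne <- shiftMat(e, -1, 1)
  w  <- shiftMat(e,  0, -1);                          eE <- shiftMat(e, 0, 1)
  sw <- shiftMat(e,  1, -1); s <- shiftMat(e,  1, 0); se <- shiftMat(e, 1, 1)
  dzdx <- ((ne + 2 * eE + se) - (nw + 2 * w + sw)) / (8 * cs_m)
  dzdy <- ((nw + 2 * n + ne) - (sw + 2 * s + se)) / (8 * cs_m)
  slope <- atan(sqrt(dzdx^2 + dzdy^2))
  aspect <- atan2(dzdy, dzdx)
  xn <- sin(slope) * sin(aspect)
  yn <- sin(slope) * cos(aspect)
  zn <- cos(slope)
  flat <- is.finite(slope) & slope == 0
  xn[flat] <- 0; yn[flat] <- 0; zn[flat] <- 1
  sum9 <- function(m) {
    acc <- matrix(0, nrow(m), ncol(m))
    for (dr in -1:1) for (dc in -1:1) acc <- acc + shiftMat(m, dr, dc)
    acc
  }
  R <- sqrt(sum9(xn)^2 + sum9(yn)^2 + sum9(zn)^2)
  vrm <- 1 - R / 9
  vrm[vrm < 0 & is.finite(vrm)] <- 0   # guard tiny negative rounding
  out <- elevation
  out@values <- vrm
  out
}

#' Exponential road distance-decay covariate
#'
#' `exp(-alpha / d)` with `d` the Euclidean distance (km) from each cell
#' centre to the nearest road segment; 0 on the road itself (the `d -> 0`
#' limit) and approaching 1 far from any road.  `alpha` sets the range over
#' which road influence persists.
#'
#' @param roads list of road polylines (two-column km matrices).
#' @param grid `RasterGrid` supplying the geometry.
#' @param alpha decay parameter in km (> 0).
#' @return list with `decay` and `dist` `RasterGrid`s.
#' @export
roadDecay <- function(roads, grid, alpha) {
  stopIfNot(alpha > 0, "alpha must be > 0")
  stopIfNot(length(roads) > 0, "empty road set: decay undefined; omit the covariate instead")
  dist <- distanceGrid(grid, roads)
  dec <- dist
  dv <- dist@values
  dec@values <- ifelse(dv <= 0, 0, exp(-alpha / dv))
  list(decay = dec, dist = dist)
}

#' Build the analysis-grain covariate stack
#'
#' Computes the four RSF covariates at the native cell size, then aggregates
#' to the analysis grain: mean for continuous layers (ruggedness, road
#' decay, road distance), mode for land-cover classes, any-touch for
#' rasterized rivers.  Ruggedness is standardized (mean 0, sd 1) after
#' aggregation.
#'
#' @param bundle a [LandscapeBundle-class].
#' @param alpha road decay parameter (km).
#' @param grain analysis cell size (km), a multiple of the native size.
#' @param includeProposed include proposed roads in the road layer (used
#'   when rebuilding surfaces under a development scenario).
#' @return a [CovariateStack-class].
#' @export
buildCovariateStack <- function(bundle, alpha, grain = 1,
                                includeProposed = FALSE) {
  cs <- bundle@cellSize
  stopIfNot(grain >= cs, "grain must be at least the native cell size")
  fct <- grain / cs
  stopIfNot(abs(fct - round(fct)) < 1e-9, "grain must be a multiple of the native cell size")
  fct <- as.integer(round(fct))
  roads <- bundle@roadsExisting
  if (includeProposed) roads <- c(roads, bundle@roadsProposed)
  stopIfNot(length(roads) > 0, "bundle has no roads")
  vrm <- vectorRuggedness(bundle@elevation)
  riv <- rasterizeLines(bundle@elevation, bundle@rivers)
  rd <- roadDecay(roads, bundle@elevation, alpha)
  z <- standardizeGrid(aggregateGrid(vrm, fct, "mean"))
  new("CovariateStack",
      ruggedness_z = z,
      river = aggregateGrid(riv, fct, "any"),
      landcover = aggregateGrid(bundle@landcover, fct, "mode"),
      road_decay = aggregateGrid(rd$decay, fct, "mean"),
      road_dist_km = aggregateGrid(rd$dist, fct, "mean"),
      alpha = alpha, grain = grain)
}

#' Extract stack covariates at point locations
#'
#' @param stack a [CovariateStack-class].
#' @param x,y coordinates (km).
#' @return data.frame with `ruggedness_z`, `river`, `road_decay`,
#'   `road_dist_km` and a `landcover` factor with reference level `"open"`;
#'   one row per point, `NA` where a point falls on nodata.
#' @export
extractCovariates <- function(stack, x, y) {
  lc <- valuesAtXY(stack@landcover, x, y)
  data.frame(
    ruggedness_z = valuesAtXY(stack@ruggedness_z, x, y),
    river = valuesAtXY(stack@river, x, y),
    road_decay = valuesAtXY(stack@road_decay, x, y),
    road_dist_km = valuesAtXY(stack@road_dist_km, x, y),
    landcover = factor(c("open", "dense", "burned", "coastal")[lc + 1],
                       levels = c("open", "dense", "burned", "coastal")))
}
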