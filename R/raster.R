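#' Construct a RasterGrid
#'
#' @param values numeric matrix (row 1 = top row); `NA` marks nodata.
#' @param xmin,ymin lower-left corner coordinates in km.
#' @param cellSize cell edge length in km.
#' @param crs opaque CRS tag (carried, never interpreted).
#' @return a [RasterGrid-class] object.
#' @examples
#' g <- rasterGrid(matrix(1:12, 3, 4))
#' dim(g)
#' @export
rasterGrid <- function(values, xmin = 0, ymin = 0, cellSize = 1, crs = "") {
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, xmin = as.numeric(xmin),
      ymin = as.numeric(ymin), cellSize = as.numeric(cellSize),
      crs = as.character(crs))
}

#' Raster cell values
#'
#' @param x a `RasterGrid`.
#' @param value replacement matrix of identical shape.
#' @return the value matrix (row 1 = top).
#' @rdname gridValues
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @rdname gridValues
#' @export
setReplaceMethod("gridValues", "RasterGrid", function(x, value) {
  stopIfNot(identical(dim(value), dim(x@values)),
            "replacement values must keep the raster shape")
  x@values <- value
  validObject(x)
  x
})

#' Raster extent
#' @param x a `RasterGrid`.
#' @return named numeric `c(xmin, xmax, ymin, ymax)` in km.
#' @rdname gridExtent
#' @export
setMethod("gridExtent", "RasterGrid", function(x) {
  d <- dim(x@values)
  c(xmin = x@xmin, xmax = x@xmin + d[2] * x@cellSize,
    ymin = x@ymin, ymax = x@ymin + d[1] * x@cellSize)
})

#' Raster cell size (km)
#' @param x a `RasterGrid`.
#' @rdname cellSize
#' @export
setMethod("cellSize", "RasterGrid", function(x) x@cellSize)

#' @export
setMethod("dim", "RasterGrid", function(x) dim(x@values))

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  v <- object@values[is.finite(object@values)]
  cat(sprintf("RasterGrid: %d x %d cells, cell %.3g km\n", d[1], d[2],
              object@cellSize))
  e <- gridExtent(object)
  cat(sprintf("  extent: x [%.6g, %.6g]  y [%.6g, %.6g] km\n",
              e["xmin"], e["xmax"], e["ymin"], e["ymax"]))
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], %d/%d valid\n", min(v), max(v),
                length(v), prod(d)))
  else cat("  values: all nodata\n")
})

setMethod("show", "TelemetryTrack", function(object) {
  cat(sprintf("TelemetryTrack %s, %s %d: %d fixes\n", object@animalId,
              object@season, object@year, nrow(object@fixes)))
})

#' @rdname trackFixes
#' @export
setMethod("trackFixes", "TelemetryTrack", function(x) x@fixes)

setMethod("show", "RSFFit", function(object) {
  cat(sprintf("RSFFit '%s' (%s): n = %d, k = %d, AICc = %.2f, %s\n",
              object@label,
              if (object@randomEffects) "GLMM" else "GLM",
              as.integer(object@n), as.integer(object@k), object@aicc,
              if (object@converged) "converged" else "NOT converged"))
  tab <- cbind(Estimate = object@coefficients, SE = object@se)
  print(round(tab, 4))
})

setMethod("show", "ResistanceSurface", function(object) {
  v <- object@raster@values[is.finite(object@raster@values)]
  cat(sprintf("ResistanceSurface %s%s: range [%.4g, %.4g]\n",
              object@scenario, if (object@stretched) " (stretched)" else "",
              min(v), max(v)))
})

setMethod("show", "CircuitSolution", function(object) {
  cat(sprintf(
    "CircuitSolution: R_eff = %.6g, residual = %.3g, injection = %g\n",
    object@effectiveResistance, object@residual, object@injection))
})

#' @rdname effectiveResistance
#' @export
setMethod("effectiveResistance", "CircuitSolution",
          function(x) x@effectiveResistance)

#' Node current-density raster of a circuit solution
#' @param x a `CircuitSolution`.
#' @rdname currentMap
#' @export
setMethod("currentMap", "CircuitSolution", function(x) x@currentMap)

setMethod("show", "PopulationMap", function(object) {
  cat(sprintf("PopulationMap (%s, %s): %d individuals\n", object@season,
              object@roadsVariant, object@nIndividuals))
})

# ---- cell arithmetic ------------------------------------------------------

#' Locate the cells containing point coordinates
#'
#' @param grid a `RasterGrid`.
#' @param x,y point coordinates in km (vectors of equal length).
#' @return integer matrix with columns `row`, `col`; `NA` rows for points
#'   outside the extent.  Cells are half-open intervals: a point exactly on
#'   a shared cell edge belongs to the cell to its east / south.
#' @export
cellFromXY <- function(grid, x, y) {
  d <- dim(grid@values)
  cs <- grid@cellSize
  col <- floor((x - grid@xmin) / cs) + 1
  ytop <- grid@ymin + d[1] * cs
  row <- floor((ytop - y) / cs) + 1
  bad <- !is.finite(row) | !is.finite(col) |
    row < 1 | row > d[1] | col < 1 | col > d[2]
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Cell-centre coordinates
#'
#' @param grid a `RasterGrid`.
#' @param row,col cell indices (vectors of equal length).
#' @return matrix with columns `x`, `y` (km) of cell centres.
#' @export
xyFromCell <- function(grid, row, col) {
  d <- dim(grid@values)
  cs <- grid@cellSize
  cbind(x = grid@xmin + (col - 0.5) * cs,
        y = grid@ymin + (d[1] - row + 0.5) * cs)
}

#' Extract raster values at point coordinates
#'
#' @inheritParams cellFromXY
#' @return numeric vector; `NA` for points outside the extent or on nodata.
#' @export
valuesAtXY <- function(grid, x, y) {
  rc <- cellFromXY(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, 1])
  out[ok] <- grid@values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Aggregate a raster to a coarser grain
#'
#' Blocks of `factor` x `factor` native cells are collapsed to one cell.
#' `"mean"` averages valid cells (continuous layers), `"mode"` takes the
#' most frequent value (class layers, ties to the smallest class), `"any"`
#' flags blocks containing any positive cell (rasterized line layers).
#'
#' @param grid a `RasterGrid`.
#' @param factor integer aggregation factor (>= 1).
#' @param fun `"mean"`, `"mode"` or `"any"`.
#' @return a `RasterGrid` at `factor` times the cell size.  Partial blocks
#'   at the east/south margin aggregate whatever cells they contain.
#' @export
aggregateGrid <- function(grid, factor, fun = c("mean", "mode", "any")) {
  fun <- match.arg(fun)
  factor <- as.integer(factor)
  stopIfNot(factor >= 1L, "aggregation factor must be >= 1")
  if (factor == 1L) return(grid)
  v <- grid@values
  d <- dim(v)
  nr <- ceiling(d[1] / factor); nc <- ceiling(d[2] / factor)
  ri <- rep(seq_len(nr), each = factor, length.out = d[1])
  ci <- rep(seq_len(nc), each = factor, length.out = d[2])
  out <- matrix(NA_real_, nr, nc)
  idx <- interaction(ri[row(v)], ci[col(v)], drop = FALSE)
  agg <- switch(fun,
    mean = tapply(v, idx, function(z) {
      z <- z[is.finite(z)]
      if (length(z)) mean(z) else NA_real_
    }),
    mode = tapply(v, idx, function(z) {
      z <- z[is.finite(z)]
      if (!length(z)) return(NA_real_)
      tt <- table(z)
      as.numeric(names(tt)[which.max(tt)])
    }),
    any = tapply(v, idx, function(z) {
      z <- z[is.finite(z)]
      if (!length(z)) return(NA_real_)
      as.numeric(any(z > 0))
    }))
  out[] <- matrix(agg, nr, nc)
  # y origin shifts so the top-left corners coincide
  ytop <- grid@ymin + d[1] * grid@cellSize
  newcs <- grid@cellSize * factor
  rasterGrid(out, xmin = grid@xmin, ymin = ytop - nr * newcs,
             cellSize = newcs, crs = grid@crs)
}

#' Standardize a raster to zero mean and unit variance
#'
#' @param grid a `RasterGrid`.
#' @return the standardized grid (nodata untouched).  Constant layers are
#'   returned as all zero.
#' @export
standardizeGrid <- function(grid) {
  v <- grid@values
  ok <- is.finite(v)
  mu <- mean(v[ok]); s <- stats::sd(v[ok])
  v[ok] <- if (is.na(s) || s == 0) 0 else (v[ok] - mu) / s
  grid@values <- v
  grid
}
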