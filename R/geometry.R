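# Planar geometry helpers for polylines (two-column vertex matrices, km).

# Squared distance from points (px, py) to segment (x1,y1)-(x2,y2).
segDist2 <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  t <- if (L2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
  qx <- x1 + t * dx; qy <- y1 + t * dy
  (px - qx)^2 + (py - qy)^2
}

#' Distance from points to the nearest polyline
#'
#' Exact point-to-segment Euclidean distance against every segment of every
#' polyline, in the units of the coordinates (km throughout the package).
#'
#' @param x,y point coordinates (equal-length vectors).
#' @param lines list of polylines, each a two-column vertex matrix.
#' @return numeric vector of distances (km).
#' @export
distanceToLines <- function(x, y, lines) {
  stopIfNot(length(lines) > 0, "empty line set: distance undefined")
  best <- rep(Inf, length(x))
  for (ln in lines) {
    ln <- as.matrix(ln)
    if (nrow(ln) == 1L) {
      best <- pmin(best, (x - ln[1, 1])^2 + (y - ln[1, 2])^2)
      next
    }
    for (s in seq_len(nrow(ln) - 1L)) {
      best <- pmin(best, segDist2(x, y, ln[s, 1], ln[s, 2],
                                  ln[s + 1, 1], ln[s + 1, 2]))
    }
  }
  sqrt(best)
}

#' Distance-to-lines raster
#'
#' @param grid a `RasterGrid` supplying the geometry.
#' @param lines list of polylines (two-column matrices, km).
#' @return `RasterGrid` of cell-centre distances (km).
#' @export
distanceGrid <- function(grid, lines) {
  d <- dim(grid@values)
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  xy <- xyFromCell(grid, rc$row, rc$col)
  dist <- distanceToLines(xy[, 1], xy[, 2], lines)
  out <- grid
  out@values <- matrix(dist, d[1], d[2])
  out
}

#' Rasterize polylines onto a grid
#'
#' A cell is flagged 1 when any line passes within half a cell diagonal of
#' its centre ("any-touch" at the native grain).
#'
#' @param grid a `RasterGrid` supplying the geometry.
#' @param lines list of polylines.
#' @return 0/1 `RasterGrid`.
#' @export
rasterizeLines <- function(grid, lines) {
  dg <- distanceGrid(grid, lines)
  tol <- grid@cellSize * sqrt(2) / 2
  dg@values <- (dg@values <= tol) * 1
  dg
}

# Random meandering polyline spanning the extent; axis = "ns" runs north to
# south, "ew" west to east.  Used by the landscape generator.
meanderLine <- function(extent, axis = c("ns", "ew"), wiggle = 0.1,
                        anchor = 0.5, nseg = 40) {
  axis <- match.arg(axis)
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  if (axis == "ns") {
    yy <- seq(extent[4], extent[3], length.out = nseg)
    xx <- extent[1] + anchor * w +
      cumsum(c(0, rnorm(nseg - 1, 0, wiggle * w / sqrt(nseg))))
    xx <- pmin(pmax(xx, extent[1]), extent[2])
    cbind(xx, yy)
  } else {
    xx <- seq(extent[1], extent[2], length.out = nseg)
    yy <- extent[3] + anchor * h +
      cumsum(c(0, rnorm(nseg - 1, 0, wiggle * h / sqrt(nseg))))
    yy <- pmin(pmax(yy, extent[3]), extent[4])
    cbind(xx, yy)
  }
}
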