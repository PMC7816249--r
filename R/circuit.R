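# Raster circuit-theory engine.  Valid cells are nodes of a weighted graph;
# each cell is joined to its 8 nearest neighbours by a resistor whose value
# is the mean of the two half-cell resistances, scaled by sqrt(2) for
# diagonal (centre-to-centre distance) steps.  Current injected at a
# migration's start cell and extracted at its end cell yields per-cell
# current densities proportional to expected random-walker visitation.

#' Build the 8-neighbour conductance graph of a resistance raster
#'
#' Orthogonal neighbours get conductance `g = 2/(r_i + r_j)`; diagonal
#' neighbours `g = 2/(sqrt(2) (r_i + r_j))`.  Nodata cells are excluded
#' together with all incident edges.
#'
#' @param resistance a `RasterGrid` (strictly positive on valid cells) or a
#'   [ResistanceSurface-class].
#' @return a `CircuitGraph` (classed list) with the node table (`row`,
#'   `col`), the edge table (`i`, `j`, `g`), the sparse graph Laplacian and
#'   the source geometry.
#' @export
buildGraph <- function(resistance) {
  if (is(resistance, "ResistanceSurface")) resistance <- resistance@raster
  r <- resistance@values
  stopIfNot(all(r[is.finite(r)] > 0), "resistance must be > 0 on valid cells")
  d <- dim(r)
  valid <- which(is.finite(r))
  stopIfNot(length(valid) > 0, "all-nodata resistance raster")
  nodeId <- matrix(NA_integer_, d[1], d[2])
  nodeId[valid] <- seq_along(valid)
  rows <- ((valid - 1) %% d[1]) + 1
  cols <- ((valid - 1) %/% d[1]) + 1
  offs <- list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
  ei <- list(); ej <- list(); eg <- list()
  for (o in offs) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 1 & r2 <= d[1] & c2 >= 1 & c2 <= d[2]
    j <- rep(NA_integer_, length(valid))
    j[ok] <- nodeId[cbind(r2[ok], c2[ok])]
    keep <- !is.na(j)
    if (!any(keep)) next
    ri <- r[valid[keep]]
    rj <- r[cbind(r2[keep], c2[keep])]
    ei[[length(ei) + 1L]] <- seq_along(valid)[keep]
    ej[[length(ej) + 1L]] <- j[keep]
    eg[[length(eg) + 1L]] <- 2 / (o[3] * (ri + rj))
  }
  i <- unlist(ei); j <- unlist(ej); g <- unlist(eg)
  nv <- length(valid)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(g, g),
                            dims = c(nv, nv))
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  structure(list(nodes = data.frame(row = rows, col = cols, cell = valid),
                 edges = data.frame(i = i, j = j, g = g),
                 laplacian = L, dim = d, grid = resistance),
            class = "CircuitGraph")
}

#' @export
print.CircuitGraph <- function(x, ...) {
  cat(sprintf("CircuitGraph: %d nodes, %d edges on a %d x %d raster\n",
              nrow(x$nodes), nrow(x$edges), x$dim[1], x$dim[2]))
  invisible(x)
}

nodeFromRowCol <- function(graph, row, col) {
  hit <- which(graph$nodes$row == row & graph$nodes$col == col)
  if (!length(hit)) NA_integer_ else hit[1]
}

#' Solve a pairwise circuit problem
#'
#' Solves the grounded graph Laplacian system `L v = b` with `+injection`
#' at the source node, `-injection` at the ground node and ground voltage
#' fixed at 0, then derives branch currents `i = g (v_i - v_j)`, the node
#' current density (half the sum of absolute incident branch currents at
#' interior nodes; the injection value at the terminals) and the effective
#' resistance `v_source / injection`.
#'
#' @param graph a `CircuitGraph` from [buildGraph()], or anything
#'   [buildGraph()] accepts.
#' @param source,ground `c(row, col)` cell indices of the terminals.
#' @param injection injected current (default 1).
#' @param tolerance maximum allowed relative Kirchhoff residual at
#'   non-terminal nodes (default 1e-8).
#' @return a [CircuitSolution-class].
#' @export
solveCircuit <- function(graph, source, ground, injection = 1,
                         tolerance = 1e-8) {
  if (!inherits(graph, "CircuitGraph")) graph <- buildGraph(graph)
  s <- nodeFromRowCol(graph, source[1], source[2])
  gnd <- nodeFromRowCol(graph, ground[1], ground[2])
  stopIfNot(!is.na(s) && !is.na(gnd), "terminal cell is nodata")
  stopIfNot(s != gnd, "source and ground must differ")
  L <- graph$laplacian
  nv <- nrow(graph$nodes)
  # connectivity check via BFS over the edge table
  comp <- componentOf(graph, s)
  if (!comp[gnd]) {
    sz <- sum(comp)
    stop(sprintf(paste0("source and ground are in different components ",
                        "(source component: %d nodes, other nodes: %d)"),
                 sz, nv - sz), call. = FALSE)
  }
  b <- rep(0, nv)
  b[s] <- injection; b[gnd] <- -injection
  keep <- setdiff(seq_len(nv), gnd)
  Lr <- L[keep, keep, drop = FALSE]
  v <- rep(0, nv)
  sol <- Matrix::solve(Matrix::forceSymmetric(Lr), b[keep])
  v[keep] <- as.numeric(sol)
  # iterative refinement if the direct solve left excess residual
  for (it in 1:3) {
    res <- b[keep] - as.numeric(Lr %*% v[keep])
    if (max(abs(res)) <= tolerance * abs(injection)) break
    v[keep] <- v[keep] +
      as.numeric(Matrix::solve(Matrix::forceSymmetric(Lr), res))
  }
  full <- as.numeric(L %*% v) - b
  nonterm <- setdiff(seq_len(nv), c(s, gnd))
  residual <- if (length(nonterm)) max(abs(full[nonterm])) else 0
  e <- graph$edges
  ecur <- e$g * (v[e$i] - v[e$j])
  dens <- numeric(nv)
  acc <- tapply(c(abs(ecur), abs(ecur)), c(e$i, e$j), sum)
  dens[as.integer(names(acc))] <- 0.5 * as.numeric(acc)
  dens[c(s, gnd)] <- abs(injection)
  cm <- graph$grid
  m <- matrix(NA_real_, graph$dim[1], graph$dim[2])
  m[graph$nodes$cell] <- dens
  cm@values <- m
  new("CircuitSolution", voltages = v, currentMap = cm,
      effectiveResistance = v[s] / injection, residual = residual,
      sourceCell = as.integer(graph$nodes$cell[s]),
      groundCell = as.integer(graph$nodes$cell[gnd]),
      injection = injection)
}

componentOf <- function(graph, start) {
  nv <- nrow(graph$nodes)
  adj <- split(c(graph$edges$j, graph$edges$i),
               c(graph$edges$i, graph$edges$j))
  seen <- logical(nv)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

# Snap a point to the nearest valid cell within `radius` cells.
snapToValid <- function(grid, x, y, radius = 5) {
  rc <- cellFromXY(grid, x, y)
  d <- dim(grid@values)
  if (!is.na(rc[1, 1]) && is.finite(grid@values[rc[1, 1], rc[1, 2]]))
    return(c(rc[1, 1], rc[1, 2]))
  r0 <- min(max(1L, rc[1, 1], na.rm = TRUE), d[1])
  c0 <- min(max(1L, rc[1, 2], na.rm = TRUE), d[2])
  cand <- expand.grid(row = max(1, r0 - radius):min(d[1], r0 + radius),
                      col = max(1, c0 - radius):min(d[2], c0 + radius))
  cand <- cand[is.finite(grid@values[cbind(cand$row, cand$col)]), ]
  if (!nrow(cand)) return(NULL)
  xy <- xyFromCell(grid, cand$row, cand$col)
  k <- which.min((xy[, 1] - x)^2 + (xy[, 2] - y)^2)
  if (sqrt((xy[k, 1] - x)^2 + (xy[k, 2] - y)^2) >
      radius * grid@cellSize * sqrt(2)) return(NULL)
  c(cand$row[k], cand$col[k])
}

#' Current-density map for one individual's migration
#'
#' Snaps the migration's start and end points to the nearest valid cell
#' (within `snapRadius` cells), solves the pairwise circuit with the start
#' as source and end as ground, and returns the node current-density map.
#'
#' @param surface a [ResistanceSurface-class] (or `RasterGrid`) to solve on,
#'   or a prebuilt `CircuitGraph`.
#' @param window a [MigrationWindow-class] supplying start/end coordinates.
#' @param injection injected current.
#' @param tolerance solver tolerance.
#' @param snapRadius maximum snap distance in cells.
#' @return a [CircuitSolution-class].
#' @export
individualCurrentMap <- function(surface, window, injection = 1,
                                 tolerance = 1e-8, snapRadius = 5) {
  graph <- if (inherits(surface, "CircuitGraph")) surface else
    buildGraph(surface)
  src <- snapToValid(graph$grid, window@startPoint[1], window@startPoint[2],
                     snapRadius)
  gnd <- snapToValid(graph$grid, window@endPoint[1], window@endPoint[2],
                     snapRadius)
  if (is.null(src) || is.null(gnd))
    stop(sprintf("no valid cell within %d cells of a migration endpoint",
                 snapRadius), call. = FALSE)
  solveCircuit(graph, src, gnd, injection, tolerance)
}
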