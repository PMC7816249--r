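test_that("graph construction yields the lattice edge count and the
           average-resistance conductances", {
  g3 <- buildGraph(rasterGrid(matrix(1, 3, 3)))
  # m(n-1) + n(m-1) + 2(m-1)(n-1) = 6 + 6 + 8
  expect_equal(nrow(g3$edges), 20)
  orth <- g3$edges$g[abs(g3$nodes$row[g3$edges$i] - g3$nodes$row[g3$edges$j]) +
                       abs(g3$nodes$col[g3$edges$i] - g3$nodes$col[g3$edges$j]) == 1]
  diag <- g3$edges$g[abs(g3$nodes$row[g3$edges$i] - g3$nodes$row[g3$edges$j]) +
                       abs(g3$nodes$col[g3$edges$i] - g3$nodes$col[g3$edges$j]) == 2]
  expect_true(all(orth == 1))
  expect_equal(unique(diag), 1 / sqrt(2), tolerance = 1e-15)
  # general m x n count
  for (dims in list(c(4, 5), c(2, 7))) {
    m <- dims[1]; n <- dims[2]
    g <- buildGraph(rasterGrid(matrix(1, m, n)))
    expect_equal(nrow(g$edges), m * (n - 1) + n * (m - 1) + 2 * (m - 1) * (n - 1))
  }
  # nodata centre removes its 8 incident edges
  m <- matrix(1, 3, 3); m[2, 2] <- NA
  expect_equal(nrow(buildGraph(rasterGrid(m))$edges), 12)
  expect_error(buildGraph(rasterGrid(matrix(NA_real_, 2, 2))), "all-nodata")
  expect_error(buildGraph(rasterGrid(matrix(-1, 2, 2))), "> 0")
})

test_that("series and diagonal unit circuits match closed forms and obey
           Kirchhoff's law", {
  sol <- solveCircuit(rasterGrid(matrix(1, 1, 3)), c(1, 1), c(1, 3))
  expect_equal(effectiveResistance(sol), 2, tolerance = 1e-10)
  expect_equal(gridValues(currentMap(sol))[1, 2], 1, tolerance = 1e-10)
  expect_lt(sol@residual, 1e-6)
  # 2x2, diagonal terminals: R_eff = 2 - sqrt(2); off-terminal symmetry
  sol2 <- solveCircuit(rasterGrid(matrix(1, 2, 2)), c(1, 1), c(2, 2))
  expect_equal(effectiveResistance(sol2), 2 - sqrt(2), tolerance = 1e-10)
  g <- buildGraph(rasterGrid(matrix(1, 2, 2)))
  off <- which(!(g$nodes$row == g$nodes$col))  # (1,2) and (2,1)
  expect_equal(sol2@voltages[off[1]], sol2@voltages[off[2]],
               tolerance = 1e-12)
})

test_that("the sparse solver agrees with a dense direct solve on random
           grids with nodata holes", {
  set.seed(31)
  for (rep in 1:6) {
    nr <- sample(4:9, 1); nc <- sample(4:9, 1)
    m <- matrix(exp(rnorm(nr * nc, 0, 1.5)), nr, nc)
    if (rep > 3) m[sample(length(m), 3)] <- NA  # punch holes
    g <- rasterGrid(m)
    valid <- which(is.finite(m), arr.ind = TRUE)
    src <- valid[1, ]; gnd <- valid[nrow(valid), ]
    gr <- buildGraph(g)
    if (!componentOf(gr, 1)[nrow(gr$nodes)]) next
    sol <- solveCircuit(gr, src, gnd)
    ora <- denseCircuitOracle(g, src, gnd)
    expect_equal(effectiveResistance(sol), ora$reff, tolerance = 1e-8)
    expect_equal(sol@voltages, ora$voltages, tolerance = 1e-8)
    expect_lt(sol@residual, 1e-6)
  }
})

test_that("reciprocity: swapping terminals preserves effective resistance
           and negates voltages", {
  set.seed(33)
  g <- rasterGrid(matrix(exp(rnorm(49)), 7, 7))
  a <- solveCircuit(g, c(1, 1), c(7, 7))
  b <- solveCircuit(g, c(7, 7), c(1, 1))
  expect_equal(effectiveResistance(a), effectiveResistance(b),
               tolerance = 1e-10)
  # voltages grounded at different nodes: compare after recentring
  expect_equal(a@voltages - mean(a@voltages),
               -(b@voltages - mean(b@voltages)), tolerance = 1e-9)
})

test_that("Rayleigh monotonicity: raising one cell's resistance never
           lowers effective resistance", {
  set.seed(35)
  for (rep in 1:5) {
    m <- matrix(exp(rnorm(100, 0, 1)), 10, 10)
    base <- effectiveResistance(solveCircuit(rasterGrid(m), c(1, 1), c(10, 10)))
    k <- sample(100, 1)
    m2 <- m; m2[k] <- m2[k] * 10
    up <- effectiveResistance(solveCircuit(rasterGrid(m2), c(1, 1), c(10, 10)))
    expect_gte(up, base - 1e-10)
  }
})

test_that("current maps are invariant to uniform resistance scaling and
           symmetric under mirrored terminals on uniform resistance", {
  set.seed(37)
  m <- matrix(exp(rnorm(64)), 8, 8)
  s1 <- solveCircuit(rasterGrid(m), c(2, 2), c(7, 7))
  s2 <- solveCircuit(rasterGrid(m / 2), c(2, 2), c(7, 7))
  expect_equal(gridValues(currentMap(s1)), gridValues(currentMap(s2)),
               tolerance = 1e-9)
  # voltages halve with resistances
  expect_equal(s2@voltages, s1@voltages / 2, tolerance = 1e-9)
  u <- solveCircuit(rasterGrid(matrix(1, 9, 9)), c(2, 5), c(8, 5))
  cm <- gridValues(currentMap(u))
  expect_equal(cm, cm[9:1, ], tolerance = 1e-6)   # mirror about mid-row
})

test_that("disconnected terminals raise an error naming component sizes
           and endpoint snapping respects the radius", {
  m <- matrix(1, 5, 5); m[, 3] <- NA
  expect_error(solveCircuit(rasterGrid(m), c(1, 1), c(1, 5)),
               "different components.*10 nodes.*10")
  # window endpoints on valid cells need no snap; far endpoints fail
  g <- rasterGrid(matrix(1, 10, 10))
  win <- new("MigrationWindow", startIndex = 1L, endIndex = 2L,
             startPoint = c(0.5, 9.5), endPoint = c(9.5, 0.5),
             nsd = c(0, 100))
  sol <- individualCurrentMap(g, win)
  expect_equal(sol@sourceCell, 1L)   # (0.5, 9.5) is the centre of cell (1,1)
  m2 <- matrix(1, 20, 20); m2[1:10, 1:10] <- NA
  win2 <- new("MigrationWindow", startIndex = 1L, endIndex = 2L,
              startPoint = c(1, 19), endPoint = c(19, 1), nsd = c(0, 100))
  expect_error(individualCurrentMap(rasterGrid(m2), win2, snapRadius = 3),
               "no valid cell within")
})
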