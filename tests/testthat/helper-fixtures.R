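# Shared fixture builders; everything is generated in code at test time.

# coefficients in the direction of the season-level selection pattern:
# avoid rugged terrain, rivers, dense/burned/coastal cover; select areas
# far from roads
refCoefs <- c(ruggedness_z = -0.22, river = -0.56, road_decay = 2.45,
              landcoverdense = -1.17, landcoverburned = -0.26,
              landcovercoastal = -2.82)

smallStudy <- function(seed = 1, extent = c(0, 40, 0, 40), nAnimals = 3,
                       scenario = "r3", selectionStrength = 2) {
  cfg <- simulationConfig(seed = seed, nAnimals = nAnimals,
                          selectionStrength = selectionStrength)
  bundle <- generateLandscape(cfg, extent = extent)
  stack <- buildCovariateStack(bundle, alpha = 30)
  hs <- predictSuitability(syntheticFit(refCoefs), stack)
  res <- buildResistance(hs, scenario)
  list(cfg = cfg, bundle = bundle, stack = stack, hs = hs, res = res)
}

# uniform suitability raster in (0, 1]
hsGrid <- function(v, nr = 5, nc = 5) rasterGrid(matrix(v, nr, nc))

# dense reference Laplacian solve: independent oracle for the circuit engine
denseCircuitOracle <- function(resistance, source, ground, injection = 1) {
  r <- resistance@values
  d <- dim(r)
  valid <- which(is.finite(r))
  id <- matrix(NA_integer_, d[1], d[2])
  id[valid] <- seq_along(valid)
  nv <- length(valid)
  G <- matrix(0, nv, nv)
  rows <- ((valid - 1) %% d[1]) + 1
  cols <- ((valid - 1) %/% d[1]) + 1
  for (k in seq_len(nv)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- rows[k] + dr; c2 <- cols[k] + dc
      if (r2 < 1 || r2 > d[1] || c2 < 1 || c2 > d[2]) next
      j <- id[r2, c2]
      if (is.na(j)) next
      dist <- if (dr != 0 && dc != 0) sqrt(2) else 1
      G[k, j] <- 2 / (dist * (r[valid[k]] + r[valid[j]]))
    }
  }
  L <- diag(rowSums(G)) - G
  s <- id[source[1], source[2]]; g <- id[ground[1], ground[2]]
  b <- rep(0, nv); b[s] <- injection; b[g] <- -injection
  keep <- setdiff(seq_len(nv), g)
  v <- rep(0, nv)
  v[keep] <- solve(L[keep, keep], b[keep])
  list(voltages = v, reff = v[s] / injection)
}
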