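# Seeded synthetic study system: smooth terrain, categorical land cover with
# an open reference class, meandering rivers and roads, communities, and
# lattice random-walk migration tracks biased by landscape resistance.
# Downstream stages are tested against these generated data.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study system.  One seed fixes all
#' stochastic output bit-for-bit; every generator routes its randomness
#' through a private RNG stream derived from it.
#'
#' @param seed integer master seed.
#' @param nAnimals number of collared animals.
#' @param yearsPerAnimal migrations simulated per animal.
#' @param fixIntervalHours nominal fix spacing (8 h, matching GPS collar
#'   duty cycle).
#' @param residencyDuration fixes spent in seasonal range before and after
#'   migration (>= 2).
#' @param migrationDuration maximum migration steps before truncation.
#' @param selectionStrength exponent on 1/resistance in the per-step
#'   preference weight (0 = resistance-blind).
#' @param goalBias concentration of the directional pull toward the
#'   destination range (0 = undirected).
#' @param season `"fall"` or `"spring"` label attached to tracks.
#' @param startRegion,endRegion `c(xmin, xmax, ymin, ymax)` rectangles (km);
#'   `NULL` defaults to central strips along the south and north edges.
#' @return a `SimulationConfig` (classed list).
#' @export
simulationConfig <- function(seed = 1L, nAnimals = 30L, yearsPerAnimal = 1L,
                             fixIntervalHours = 8, residencyDuration = 30L,
                             migrationDuration = 300L,
                             selectionStrength = 2, goalBias = 1,
                             season = "fall",
                             startRegion = NULL, endRegion = NULL) {
  stopIfNot(residencyDuration >= 2, "residencyDuration must be >= 2 fixes")
  stopIfNot(migrationDuration >= 2, "migrationDuration must be >= 2 fixes")
  stopIfNot(selectionStrength >= 0, "selectionStrength must be >= 0")
  structure(list(seed = as.integer(seed), nAnimals = as.integer(nAnimals),
                 yearsPerAnimal = as.integer(yearsPerAnimal),
                 fixIntervalHours = fixIntervalHours,
                 residencyDuration = as.integer(residencyDuration),
                 migrationDuration = as.integer(migrationDuration),
                 selectionStrength = selectionStrength, goalBias = goalBias,
                 season = season, startRegion = startRegion,
                 endRegion = endRegion),
            class = "SimulationConfig")
}

# Gaussian-smoothed white-noise field as an nr x nc matrix.
smoothField <- function(nr, nc, sigma) {
  noise <- matrix(rnorm(nr * nc), nr, nc)
  if (sigma <= 0) return(noise)
  band <- function(n) {
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, function(a, b) (a - b)^2) / (2 * sigma^2))
    K / rowSums(K)
  }
  band(nr) %*% noise %*% t(band(nc))
}

#' Generate a synthetic landscape bundle
#'
#' Elevation is a Gaussian-smoothed random field (so terrain ruggedness
#' varies smoothly in space), land cover is carved from a second smooth
#' field into open (reference, most frequent), dense vegetation and burned
#' classes with a coastal-water strip along the west edge, and rivers /
#' roads are meandering polylines spanning the extent.  Deterministic given
#' `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @param extent `c(xmin, xmax, ymin, ymax)` in km.
#' @param cellSize native cell size (km).
#' @param flat if TRUE, elevation is constant (downstream ruggedness is 0).
#' @param reliefM total relief of the terrain field (m).
#' @param coastalWidthKm width of the coastal-water strip (km).
#' @param proposedRoad if TRUE, include a proposed east-west road across the
#'   middle of the extent.
#' @return a [LandscapeBundle-class].
#' @export
generateLandscape <- function(config, extent = c(0, 100, 0, 100),
                              cellSize = 1, flat = FALSE, reliefM = 600,
                              coastalWidthKm = 3, proposedRoad = TRUE) {
  nc <- round((extent[2] - extent[1]) / cellSize)
  nr <- round((extent[4] - extent[3]) / cellSize)
  stopIfNot(nr >= 2 && nc >= 2, "degenerate extent: fewer than 2 cells on a side")
  withSeed(childSeed(config$seed, 11L), {
    elev <- if (flat) matrix(100, nr, nc) else {
      f <- smoothField(nr, nc, sigma = 3)
      # modulate local amplitude so ruggedness varies across the extent
      amp <- smoothField(nr, nc, sigma = 12)
      amp <- (amp - min(amp)) / (max(amp) - min(amp) + 1e-12)
      f <- f * (0.3 + 0.7 * amp)
      reliefM * (f - min(f)) / (max(f) - min(f))
    }
    eg <- rasterGrid(elev, xmin = extent[1], ymin = extent[3],
                     cellSize = cellSize, crs = "synthetic-km")
    s2 <- smoothField(nr, nc, sigma = 4)
    lc <- matrix(0, nr, nc)
    lc[s2 > quantile(s2, 0.75)] <- 1          # dense vegetation
    lc[s2 < quantile(s2, 0.10)] <- 2          # burned
    xs <- xyFromCell(eg, rep(1L, nc), seq_len(nc))[, 1]
    coastal <- xs < extent[1] + coastalWidthKm
    lc[, coastal] <- 3                        # coastal water strip
    lg <- rasterGrid(lc, xmin = extent[1], ymin = extent[3],
                     cellSize = cellSize, crs = "synthetic-km")
    rivers <- list(meanderLine(extent, "ns", wiggle = 0.08, anchor = 0.38),
                   meanderLine(extent, "ns", wiggle = 0.08, anchor = 0.68))
    roadsE <- list(meanderLine(extent, "ns", wiggle = 0.04, anchor = 0.88))
    roadsP <- if (proposedRoad)
      list(meanderLine(extent, "ew", wiggle = 0.03, anchor = 0.5)) else list()
    comm <- data.frame(
      name = c("midway", "eastside", "southport"),
      x_km = extent[1] + c(0.45, 0.80, 0.55) * (extent[2] - extent[1]),
      y_km = extent[3] + c(0.55, 0.50, 0.12) * (extent[4] - extent[3]))
    new("LandscapeBundle", elevation = eg, landcover = lg, rivers = rivers,
        roadsExisting = roadsE, roadsProposed = roadsP, communities = comm,
        extent = extent, cellSize = cellSize)
  })
}

neighborOffsets <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                         dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# default start/end regions: central strips along the south / north edges
defaultRegions <- function(extent) {
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  list(start = c(extent[1] + 0.3 * w, extent[1] + 0.7 * w,
                 extent[3] + 0.05 * h, extent[3] + 0.18 * h),
       end = c(extent[1] + 0.3 * w, extent[1] + 0.7 * w,
               extent[4] - 0.18 * h, extent[4] - 0.05 * h))
}

cellsInRegion <- function(grid, region) {
  d <- dim(grid@values)
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  xy <- xyFromCell(grid, rc$row, rc$col)
  ok <- xy[, 1] >= region[1] & xy[, 1] <= region[2] &
    xy[, 2] >= region[3] & xy[, 2] <= region[4] &
    is.finite(grid@values[cbind(rc$row, rc$col)]) &
    grid@values[cbind(rc$row, rc$col)] > 0
  rc[ok, , drop = FALSE]
}

#' Simulate migration tracks as biased lattice random walks
#'
#' Each track is range residency near the start region, a biased 8-neighbour
#' random walk toward the end region with per-step preference weight
#' proportional to `(1/resistance)^selectionStrength` times a von
#' Mises-style directional pull `exp(goalBias * cos(heading error))`, then
#' residency in the destination range.  Fixes are spaced
#' `fixIntervalHours` apart, giving the low-rise-plateau net-squared
#' displacement signature of seasonal migration.
#'
#' @param bundle a [LandscapeBundle-class] (geometry source).
#' @param resistance a `RasterGrid` of strictly positive resistance on
#'   traversable cells (`NA` = impassable).
#' @param config a [simulationConfig()].
#' @return list of [TelemetryTrack-class], one per animal-year.
#' @export
simulateTracks <- function(bundle, resistance, config) {
  regions <- defaultRegions(bundle@extent)
  startR <- if (is.null(config$startRegion)) regions$start else config$startRegion
  endR <- if (is.null(config$endRegion)) regions$end else config$endRegion
  rv <- resistance@values
  stopIfNot(all(rv[is.finite(rv)] > 0),
            "resistance must be strictly positive on traversable cells")
  d <- dim(rv)
  startCells <- cellsInRegion(resistance, startR)
  endCells <- cellsInRegion(resistance, endR)
  stopIfNot(nrow(startCells) > 0, "no traversable cell in start region")
  stopIfNot(nrow(endCells) > 0, "no traversable cell in end region")
  goal <- c(mean(xyFromCell(resistance, endCells$row, endCells$col)[, 1]),
            mean(xyFromCell(resistance, endCells$row, endCells$col)[, 2]))
  inEnd <- function(x, y) x >= endR[1] && x <= endR[2] &&
    y >= endR[3] && y <= endR[4]

  season0 <- if (config$season == "fall") "-09-01 00:00:00" else "-04-01 00:00:00"
  tracks <- list()
  for (a in seq_len(config$nAnimals)) for (yr in seq_len(config$yearsPerAnimal)) {
    id <- sprintf("A%03d", a)
    year <- 2010L + yr
    tracks[[length(tracks) + 1L]] <- withSeed(
      childSeed(config$seed, 1000L + a * 17L + yr), {
        start <- startCells[sample.int(nrow(startCells), 1L), ]
        pos <- c(start$row, start$col)
        path <- matrix(NA_integer_, 0, 2)
        stepTo <- function(pos, weightsFun) {
          nb <- cbind(pos[1] + neighborOffsets[, 1],
                      pos[2] + neighborOffsets[, 2])
          ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2]
          ok[ok] <- is.finite(rv[nb[ok, , drop = FALSE]])
          if (!any(ok)) return(NULL)
          nbok <- nb[ok, , drop = FALSE]
          w <- weightsFun(nbok, which(ok))
          if (all(w <= 0) || !any(is.finite(w))) return(NULL)
          nbok[sample.int(nrow(nbok), 1L, prob = w), ]
        }
        # residency: undirected wander tethered to the start cell and
        # confined to the seasonal range
        residencyW <- function(anchor, region) function(nb, k) {
          xyn <- xyFromCell(resistance, nb[, 1], nb[, 2])
          inR <- xyn[, 1] >= region[1] & xyn[, 1] <= region[2] &
            xyn[, 2] >= region[3] & xyn[, 2] <= region[4]
          exp(-0.5 * ((nb[, 1] - anchor[1])^2 +
                      (nb[, 2] - anchor[2])^2) / 4) * inR
        }
        wStart <- residencyW(pos, startR)
        for (i in seq_len(config$residencyDuration - 1L)) {
          nxt <- stepTo(pos, wStart)
          path <- rbind(path, pos)
          if (!is.null(nxt)) pos <- nxt
        }
        path <- rbind(path, pos)
        # migration: resistance-weighted, goal-directed walk
        steps <- 0L
        repeat {
          xy <- xyFromCell(resistance, pos[1], pos[2])
          if (inEnd(xy[1], xy[2]) || steps >= config$migrationDuration) break
          nxt <- stepTo(pos, function(nb, k) {
            xyn <- xyFromCell(resistance, nb[, 1], nb[, 2])
            vx <- xyn[, 1] - xy[1]; vy <- xyn[, 2] - xy[2]
            gx <- goal[1] - xy[1]; gy <- goal[2] - xy[2]
            gn <- sqrt(gx^2 + gy^2); sn <- sqrt(vx^2 + vy^2)
            cosang <- if (gn < 1e-9) rep(0, nrow(nb)) else
              (vx * gx + vy * gy) / (sn * gn)
            dirw <- exp(config$goalBias * cosang)
            resw <- (1 / rv[nb])^config$selectionStrength
            dirw * resw
          })
          if (is.null(nxt))
            stop(sprintf("animal %s year %d: end region unreachable (no traversable step)",
                         id, year), call. = FALSE)
          pos <- nxt
          path <- rbind(path, pos)
          steps <- steps + 1L
        }
        if (steps >= config$migrationDuration)
          warning(sprintf("animal %s year %d: migration truncated at %d steps",
                          id, year, steps))
        # residency in the destination range (confined when the walk
        # arrived; if migration was truncated short, wander in place)
        arrived <- inEnd(xyFromCell(resistance, pos[1], pos[2])[1],
                         xyFromCell(resistance, pos[1], pos[2])[2])
        wEnd <- residencyW(pos, if (arrived) endR else
          c(-Inf, Inf, -Inf, Inf))
        for (i in seq_len(config$residencyDuration)) {
          nxt <- stepTo(pos, wEnd)
          if (!is.null(nxt)) pos <- nxt
          path <- rbind(path, pos)
        }
        xy <- xyFromCell(resistance, path[, 1], path[, 2])
        t0 <- as.POSIXct(paste0(year, season0), tz = "UTC")
        ts <- t0 + (seq_len(nrow(path)) - 1L) * config$fixIntervalHours * 3600
        new("TelemetryTrack", animalId = id, season = config$season,
            year = year,
            fixes = data.frame(timestamp = ts, x_km = xy[, 1],
                               y_km = xy[, 2]))
      })
  }
  tracks
}
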