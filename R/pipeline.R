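# End-to-end orchestration: simulate -> delimit migrations -> fit RSF ->
# build resistance scenarios -> solve circuits -> rank -> aggregate ->
# assess road impacts, with every artifact written as plain text and a
# manifest recording config, seed and checksums.

knownConfigKeys <- c("seed", "outDir", "extent", "cellSize", "grain",
                     "nAnimals", "yearsPerAnimal", "residencyDuration",
                     "migrationDuration", "selectionStrength", "goalBias",
                     "season", "trueScenario", "trueAlpha",
                     "trueCoefficients", "alphaGrid", "availabilityRatio",
                     "scenarios", "stretchLo", "stretchHi", "clampEpsilon",
                     "solverTolerance", "snapRadius", "bufferRadiusKm",
                     "kFolds", "nBoot", "bins", "randomEffects")

#' Assemble and validate a pipeline configuration
#'
#' Defaults mirror the standard study design: 20 available points per used
#' location, 1-1,000 resistance stretch, 8-neighbour circuit solves,
#' 20-km community buffers, 10 validation folds and 500 bootstrap draws.
#' The synthetic stage simulates tracks on a resistance surface derived
#' from `trueScenario` applied to suitability under `trueCoefficients` and
#' `trueAlpha`, so downstream recovery is measurable.
#'
#' @param ... overrides of the named defaults; unknown keys are rejected.
#' @return a validated `PipelineConfig` (classed list).
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L, outDir = tempfile("connectscape_run_"),
    extent = c(0, 60, 0, 60), cellSize = 1, grain = 1,
    nAnimals = 12L, yearsPerAnimal = 1L, residencyDuration = 25L,
    migrationDuration = 300L, selectionStrength = 2, goalBias = 1,
    season = "fall", trueScenario = "r3", trueAlpha = 30,
    trueCoefficients = c(ruggedness_z = -0.22, river = -0.56,
                         road_decay = 2.45, landcoverdense = -1.17,
                         landcoverburned = -0.26, landcovercoastal = -2.82),
    alphaGrid = defaultAlphaGrid(), availabilityRatio = 20,
    scenarios = names(resistanceScenarios()), stretchLo = 1,
    stretchHi = 1000, clampEpsilon = 1e-3, solverTolerance = 1e-8,
    snapRadius = 5, bufferRadiusKm = 20, kFolds = 10, nBoot = 500,
    bins = 10, randomEffects = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), knownConfigKeys)
  stopIfNot(length(unknown) == 0,
            paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  stopIfNot(cfg$bufferRadiusKm > 0, "bufferRadiusKm must be > 0")
  stopIfNot(cfg$availabilityRatio >= 1, "availabilityRatio must be >= 1")
  stopIfNot(cfg$stretchHi > cfg$stretchLo, "stretch bounds inverted")
  stopIfNot(cfg$clampEpsilon > 0 && cfg$clampEpsilon < 0.1,
            "clampEpsilon must lie in (0, 0.1)")
  stopIfNot(cfg$solverTolerance > 0, "solverTolerance must be > 0")
  stopIfNot(cfg$kFolds >= 2, "kFolds must be >= 2")
  stopIfNot(all(cfg$scenarios %in% names(resistanceScenarios())),
            "scenarios must be among r0..r4")
  stopIfNot(cfg$trueScenario %in% names(resistanceScenarios()),
            "trueScenario must be one of r0..r4")
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file (`.yaml`/`.yml` or `.json`); keys as in
#'   [pipelineConfig()], unknown keys rejected.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$trueCoefficients))
    raw$trueCoefficients <- unlist(raw$trueCoefficients)
  do.call(pipelineConfig, raw)
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                paste(utils::head(format(v, digits = 4), 8), collapse = " ")))
  }
  invisible(x)
}

logStage <- function(lines, con) {
  for (l in lines) writeLines(sprintf("[%s] %s", format(Sys.time(),
                                                        "%H:%M:%S"), l), con)
}

#' Run the full connectivity pipeline
#'
#' Executes simulate, detect, fit-rsf, build-resistance, solve-circuits,
#' rank, aggregate and assess-impact in order, writing every artifact under
#' `config$outDir` (ASCII grids, CSV tables, GeoJSON features, JSON fit and
#' manifest) plus a stage-tagged log.  Rerunning with an identical config
#' reproduces all stochastic outputs bit-for-bit; the manifest records the
#' seed, package version and an md5 checksum per artifact.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) a list with the in-memory results of every stage.
#' @export
runPipeline <- function(config) {
  stopIfNot(inherits(config, "PipelineConfig"), "config must be a PipelineConfig")
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(config$outDir, f)
  logcon <- file(outp("pipeline.log"), "w")
  on.exit(close(logcon))
  seed <- config$seed

  # --- simulate ------------------------------------------------------------
  logStage("stage simulate: generating landscape and tracks", logcon)
  simcfg <- simulationConfig(seed = seed, nAnimals = config$nAnimals,
                             yearsPerAnimal = config$yearsPerAnimal,
                             residencyDuration = config$residencyDuration,
                             migrationDuration = config$migrationDuration,
                             selectionStrength = config$selectionStrength,
                             goalBias = config$goalBias,
                             season = config$season)
  bundle <- generateLandscape(simcfg, extent = config$extent,
                              cellSize = config$cellSize)
  genStack <- buildCovariateStack(bundle, alpha = config$trueAlpha,
                                  grain = config$grain)
  genFit <- syntheticFit(config$trueCoefficients)
  hsTrue <- predictSuitability(genFit, genStack)
  rTrue <- buildResistance(hsTrue, config$trueScenario, config$clampEpsilon,
                           config$stretchLo, config$stretchHi,
                           hsSource = "generator")
  tracks <- simulateTracks(bundle, rTrue@raster, simcfg)
  writeAsciiGrid(bundle@elevation, outp("elevation.asc"))
  writeAsciiGrid(bundle@landcover, outp("landcover.asc"))
  writeGeoJSON(outp("rivers.geojson"), lines = bundle@rivers)
  writeGeoJSON(outp("roads_existing.geojson"), lines = bundle@roadsExisting)
  writeGeoJSON(outp("roads_proposed.geojson"), lines = bundle@roadsProposed)
  writeGeoJSON(outp("communities.geojson"),
               points = bundle@communities)
  writeTracksCsv(tracks, outp("tracks.csv"))

  # --- detect --------------------------------------------------------------
  logStage("stage detect: delimiting migrations by NSD", logcon)
  windows <- lapply(tracks, detectMigration)
  keep <- !vapply(windows, is.null, logical(1))
  for (i in which(!keep))
    logStage(sprintf("skip %s %d: no migration detected",
                     tracks[[i]]@animalId, tracks[[i]]@year), logcon)
  mig <- migrationTable(tracks)
  stopIfNot(!is.null(mig), "stage detect: no migrations in any track")
  write.csv(mig, outp("migrations.csv"), row.names = FALSE)

  # --- fit-rsf -------------------------------------------------------------
  logStage("stage fit-rsf: availability, alpha scan, factorial selection",
           logcon)
  scanStack <- genStack   # distances don't depend on alpha
  tab0 <- buildUsedAvailable(tracks[keep], windows[keep], scanStack,
                             ratio = config$availabilityRatio,
                             seed = childSeed(seed, 21L))
  alphaSel <- selectDecayAlpha(tab0, config$alphaGrid)
  write.csv(alphaSel, outp("alpha_selection.csv"), row.names = FALSE)
  alphaHat <- alphaSel$alpha[1]
  if (is.na(alphaHat)) {
    logStage("linear distance model won the decay scan", logcon)
    alphaHat <- config$trueAlpha
  }
  stack <- buildCovariateStack(bundle, alpha = alphaHat, grain = config$grain)
  tab <- buildUsedAvailable(tracks[keep], windows[keep], stack,
                            ratio = config$availabilityRatio,
                            seed = childSeed(seed, 22L))
  vifs <- vif(cbind(ruggedness_z = tab$ruggedness_z, river = tab$river,
                    road_decay = tab$road_decay))
  sel <- selectRSFModel(tab, randomEffects = config$randomEffects)
  write.csv(sel$table, outp("model_selection.csv"), row.names = FALSE)
  topFit <- sel$fits[[sel$table$label[1]]]
  writeRSFFit(topFit, outp("rsf_fit.json"))
  kv <- kfoldValidate(tab, formulaOf(topFit, sel), k = config$kFolds,
                      bins = config$bins, seed = childSeed(seed, 23L),
                      randomEffects = config$randomEffects)
  logStage(sprintf("rsf k-fold mean rho = %.3f", kv$mean_rho), logcon)

  # --- build-resistance ----------------------------------------------------
  logStage("stage resist: scenario surfaces", logcon)
  hs <- predictSuitability(topFit, stack)
  writeAsciiGrid(hs, outp("suitability.asc"))
  surfaces <- lapply(setNames(config$scenarios, config$scenarios),
                     function(s) buildResistance(hs, s, config$clampEpsilon,
                                                 config$stretchLo,
                                                 config$stretchHi,
                                                 hsSource = "top_model"))
  for (s in names(surfaces))
    writeAsciiGrid(surfaces[[s]]@raster, outp(sprintf("resistance_%s.asc", s)))

  # --- solve-circuits + rank ----------------------------------------------
  logStage("stage solve/rank: pairwise circuits per individual x scenario",
           logcon)
  graphs <- lapply(surfaces, buildGraph)
  keptTracks <- tracks[keep]; keptWins <- windows[keep]
  rankings <- list(); topMaps <- list(); fixesBy <- list()
  for (i in seq_along(keptTracks)) {
    tr <- keptTracks[[i]]; win <- keptWins[[i]]
    id <- sprintf("%s-%s-%d", tr@animalId, tr@season, tr@year)
    maps <- tryCatch(
      lapply(graphs, function(g)
        currentMap(individualCurrentMap(g, win,
                                        tolerance = config$solverTolerance,
                                        snapRadius = config$snapRadius))),
      error = function(e) {
        logStage(sprintf("skip %s: %s", id, conditionMessage(e)), logcon)
        NULL
      })
    if (is.null(maps)) next
    fx <- tr@fixes[win@startIndex:win@endIndex, ]
    rk <- rankIndividual(maps, fx, id)
    rankings[[length(rankings) + 1L]] <- rk
    topMaps[[length(topMaps) + 1L]] <- maps[[rk$top]]
    fixesBy[[length(fixesBy) + 1L]] <- fx
  }
  stopIfNot(length(rankings) > 0, "stage rank: no individual could be solved")
  rankTab <- do.call(rbind, lapply(rankings, function(r)
    data.frame(id = r$id, top = r$top, tie = r$tie,
               t(as.matrix(r$scores[names(resistanceScenarios())])))))
  write.csv(rankTab, outp("rankings.csv"), row.names = FALSE)
  support <- tabulateSupport(rankings)
  write.csv(support, outp("scenario_support.csv"), row.names = FALSE)

  # --- aggregate -----------------------------------------------------------
  logStage("stage aggregate: population map + validation", logcon)
  popBase <- populationMap(topMaps, season = config$season, "baseline")
  writeAsciiGrid(popBase@raster, outp("population_baseline.asc"))
  popVal <- validatePopulationMap(topMaps, fixesBy, k = config$kFolds,
                                  bins = config$bins,
                                  seed = childSeed(seed, 31L),
                                  season = config$season)
  logStage(sprintf("population map mean rho = %.3f", popVal$mean_rho), logcon)

  # --- impact --------------------------------------------------------------
  logStage("stage impact: proposed roads and community effect sizes", logcon)
  roadMaps <- list()
  if (length(bundle@roadsProposed)) {
    rebuilt <- lapply(setNames(config$scenarios, config$scenarios),
                      function(s) rebuildWithRoads(topFit, bundle, alphaHat,
                                                   config$grain, s,
                                                   config$clampEpsilon,
                                                   config$stretchLo,
                                                   config$stretchHi)$surface)
    rGraphs <- lapply(rebuilt, buildGraph)
    j <- 0L
    for (i in seq_along(keptTracks)) {
      tr <- keptTracks[[i]]; win <- keptWins[[i]]
      id <- sprintf("%s-%s-%d", tr@animalId, tr@season, tr@year)
      if (!any(vapply(rankings, function(r) r$id == id, logical(1)))) next
      j <- j + 1L
      top <- rankings[[j]]$top
      sol <- tryCatch(individualCurrentMap(rGraphs[[top]], win,
                                           tolerance = config$solverTolerance,
                                           snapRadius = config$snapRadius),
                      error = function(e) {
                        logStage(sprintf("skip %s (with roads): %s", id,
                                         conditionMessage(e)), logcon)
                        NULL
                      })
      if (!is.null(sol)) roadMaps[[length(roadMaps) + 1L]] <- currentMap(sol)
    }
  }
  effects <- NULL; popRoads <- NULL
  if (length(roadMaps)) {
    popRoads <- populationMap(roadMaps, season = config$season,
                              "with_proposed")
    writeAsciiGrid(popRoads@raster, outp("population_with_proposed.asc"))
    effects <- communityEffects(popBase, popRoads, bundle@communities,
                                radius = config$bufferRadiusKm,
                                nBoot = config$nBoot,
                                seed = childSeed(seed, 41L))
    write.csv(effects, outp("community_effects.csv"), row.names = FALSE)
  }

  # --- manifest ------------------------------------------------------------
  cfgPath <- outp("config.json")
  jsonlite::write_json(unclass(config), cfgPath, auto_unbox = TRUE,
                       digits = NA)
  arts <- setdiff(list.files(config$outDir),
                  c("manifest.json", "pipeline.log"))
  sums <- tools::md5sum(file.path(config$outDir, arts))
  manifest <- list(seed = seed,
                   package_version = as.character(
                     utils::packageVersion("connectscape")),
                   config_md5 = unname(tools::md5sum(cfgPath)),
                   artifacts = as.list(setNames(unname(sums), arts)))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  logStage("pipeline complete", logcon)
  invisible(list(bundle = bundle, tracks = tracks, windows = windows,
                 migrations = mig, alphaSelection = alphaSel,
                 alpha = alphaHat, vif = vifs, modelSelection = sel$table,
                 fit = topFit, rsfValidation = kv, hs = hs,
                 surfaces = surfaces, rankings = rankings,
                 support = support, populationBaseline = popBase,
                 populationValidation = popVal,
                 populationWithRoads = popRoads, effects = effects,
                 manifest = manifest))
}

# look up the formula a selected fit was built from
formulaOf <- function(fit, sel) {
  fs <- candidateModelSet()
  if (fit@label %in% names(fs)) fs[[fit@label]] else
    response ~ ruggedness_z + river + road_decay + landcover
}

#' Construct an RSFFit from known coefficients
#'
#' Used by the synthetic stage (suitability under generator-truth
#' coefficients) and useful for scoring fixed models; the covariance is
#' zero and `n`/`k` are placeholders.
#'
#' @param coefficients named numeric vector on the covariate scale of
#'   [predictSuitability()].
#' @return an [RSFFit-class] flagged converged.
#' @export
syntheticFit <- function(coefficients) {
  k <- length(coefficients)
  new("RSFFit", coefficients = coefficients,
      se = setNames(rep(0, k), names(coefficients)),
      vcov = matrix(0, k, k, dimnames = list(names(coefficients),
                                             names(coefficients))),
      logLik = 0, n = k + 2, k = k, aicc = NA_real_, converged = TRUE,
      randomEffects = FALSE, ranefVar = setNames(numeric(0), character(0)),
      label = "synthetic")
}
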