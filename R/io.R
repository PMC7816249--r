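# Plain-text interchange: ESRI ASCII grids for rasters, GeoJSON for vector
# features, CSV for tracks and tables, JSON for fitted models.

#' Write a raster as an ESRI ASCII grid
#'
#' @param grid a `RasterGrid`.
#' @param path output `.asc` path.
#' @param digits significant digits written (default keeps full precision).
#' @export
writeAsciiGrid <- function(grid, path, digits = 17) {
  d <- dim(grid@values)
  hdr <- c(sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10f", grid@xmin),
           sprintf("yllcorner %.10f", grid@ymin),
           sprintf("cellsize %.10f", grid@cellSize),
           "NODATA_value -9999")
  v <- grid@values
  v[!is.finite(v)] <- -9999
  rows <- apply(v, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path an `.asc` file.
#' @param crs optional CRS tag to attach.
#' @return a `RasterGrid` (NODATA cells become `NA`).
#' @export
readAsciiGrid <- function(path, crs = "") {
  ln <- readLines(path)
  hdr <- ln[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  nr <- vals[["nrows"]]; nc <- vals[["ncols"]]
  body <- scan(text = paste(ln[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  rasterGrid(m, xmin = vals[["xllcorner"]], ymin = vals[["yllcorner"]],
             cellSize = vals[["cellsize"]], crs = crs)
}

#' Write polylines or labelled points as GeoJSON
#'
#' @param lines list of two-column vertex matrices (ignored when `points`
#'   given).
#' @param points data.frame with `name`, `x_km`, `y_km`.
#' @param path output path.
#' @export
writeGeoJSON <- function(path, lines = NULL, points = NULL) {
  feats <- list()
  for (ln in lines) {
    ln <- as.matrix(ln)
    feats[[length(feats) + 1L]] <- list(
      type = "Feature", properties = list(),
      geometry = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(ln)),
                                           function(i) as.numeric(ln[i, ]))))
  }
  if (!is.null(points)) for (i in seq_len(nrow(points))) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature", properties = list(name = points$name[i]),
      geometry = list(type = "Point",
                      coordinates = c(points$x_km[i], points$y_km[i])))
  }
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GeoJSON features written by [writeGeoJSON()]
#'
#' @param path GeoJSON file.
#' @return list with `lines` (list of matrices) and `points` (data.frame).
#' @export
readGeoJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  lines <- list(); pts <- list()
  for (f in obj$features) {
    g <- f$geometry
    if (g$type == "LineString") {
      m <- do.call(rbind, lapply(g$coordinates, function(c2)
        c(as.numeric(c2[[1]]), as.numeric(c2[[2]]))))
      lines[[length(lines) + 1L]] <- m
    } else if (g$type == "Point") {
      pts[[length(pts) + 1L]] <- data.frame(
        name = if (!is.null(f$properties$name)) f$properties$name else "",
        x_km = as.numeric(g$coordinates[[1]]),
        y_km = as.numeric(g$coordinates[[2]]))
    }
  }
  list(lines = lines,
       points = if (length(pts)) do.call(rbind, pts) else
         data.frame(name = character(0), x_km = numeric(0),
                    y_km = numeric(0)))
}

#' Write telemetry tracks to CSV
#'
#' Columns: `animal_id, season, year, timestamp_iso8601, x_km, y_km`.
#'
#' @param tracks list of `TelemetryTrack`.
#' @param path output CSV path.
#' @export
writeTracksCsv <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    f <- tr@fixes
    data.frame(animal_id = tr@animalId, season = tr@season, year = tr@year,
               timestamp_iso8601 = format(f$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                          tz = "UTC"),
               x_km = f$x_km, y_km = f$y_km)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read telemetry tracks from CSV
#'
#' @param path CSV in the [writeTracksCsv()] schema.
#' @return list of `TelemetryTrack`, one per animal-season-year.
#' @export
readTracksCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(df$animal_id, df$season, df$year, drop = TRUE)
  lapply(split(df, key), function(g) {
    ts <- as.POSIXct(g$timestamp_iso8601, format = "%Y-%m-%dT%H:%M:%SZ",
                     tz = "UTC")
    o <- order(ts)
    new("TelemetryTrack", animalId = as.character(g$animal_id[1]),
        season = g$season[1], year = as.integer(g$year[1]),
        fixes = data.frame(timestamp = ts[o], x_km = g$x_km[o],
                           y_km = g$y_km[o]))
  })
}

#' Serialize a fitted RSF model as JSON
#'
#' @param fit an `RSFFit`.
#' @param path output path.
#' @export
writeRSFFit <- function(fit, path) {
  obj <- list(label = fit@label, coefficients = as.list(fit@coefficients),
              se = as.list(fit@se), vcov = fit@vcov,
              logLik = fit@logLik, n = fit@n, k = fit@k, aicc = fit@aicc,
              converged = fit@converged, randomEffects = fit@randomEffects,
              ranefVar = as.list(fit@ranefVar),
              bootstrap = "parametric over the coefficient sampling distribution")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted RSF model from JSON
#'
#' @param path file written by [writeRSFFit()].
#' @return an `RSFFit`.
#' @export
readRSFFit <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- unlist(o$coefficients)
  vc <- as.matrix(o$vcov)
  dimnames(vc) <- list(names(cf), names(cf))
  new("RSFFit", coefficients = cf, se = unlist(o$se), vcov = vc,
      logLik = o$logLik, n = o$n, k = o$k, aicc = o$aicc,
      converged = o$converged, randomEffects = o$randomEffects,
      ranefVar = if (length(o$ranefVar)) unlist(o$ranefVar) else
        setNames(numeric(0), character(0)),
      label = o$label)
}
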