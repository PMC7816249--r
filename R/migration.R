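# Net-squared displacement and automated migration delimitation.

#' Net-squared displacement series
#'
#' Squared Euclidean distance (km^2) between a track's first fix and every
#' fix; for a seasonal migrant the series is low during range residency,
#' rises rapidly during migration and plateaus on arrival.
#'
#' @param track a [TelemetryTrack-class].
#' @return numeric vector, one value per fix; first element 0.
#' @export
nsdSeries <- function(track) {
  f <- track@fixes
  (f$x_km - f$x_km[1])^2 + (f$y_km - f$y_km[1])^2
}

#' Delimit a migration from its NSD series
#'
#' A deterministic surrogate for visual NSD inspection: the plateau level
#' `P` is the median of the top quartile of the series; migration starts at
#' the last fix before NSD first exceeds `lowFrac * P` and ends at the
#' first fix reaching `highFrac * P`.  A track whose trailing-window
#' maximum does not exceed 4x the leading-window median + 1 km^2 shows no
#' plateau and is reported as non-migratory.
#'
#' @param track a [TelemetryTrack-class] (or a numeric NSD series).
#' @param lowFrac,highFrac plateau fractions delimiting departure and
#'   arrival (defaults 0.05 and 0.95).
#' @return a [MigrationWindow-class], or `NULL` when no migration is
#'   detected.
#' @export
detectMigration <- function(track, lowFrac = 0.05, highFrac = 0.95) {
  if (is(track, "TelemetryTrack")) {
    nsd <- nsdSeries(track)
    f <- track@fixes
  } else {
    nsd <- as.numeric(track)
    f <- NULL
  }
  n <- length(nsd)
  stopIfNot(n >= 3, "need at least 3 fixes")
  stopIfNot(lowFrac > 0 && highFrac > lowFrac && highFrac <= 1,
            "need 0 < lowFrac < highFrac <= 1")
  w <- max(5L, ceiling(0.1 * n))
  lead <- nsd[seq_len(min(w, n))]
  trail <- nsd[seq.int(max(1L, n - w + 1L), n)]
  if (max(trail) <= 4 * median(lead) + 1) return(NULL)  # no migration detected
  P <- median(nsd[nsd >= quantile(nsd, 0.75)])
  if (P <= 0) return(NULL)
  firstAbove <- which(nsd > lowFrac * P)[1]
  if (is.na(firstAbove)) return(NULL)
  start <- max(1L, firstAbove - 1L)
  end <- which(nsd >= highFrac * P)[1]
  if (is.na(end) || end <= start) return(NULL)
  sp <- if (is.null(f)) c(NA_real_, NA_real_) else
    c(f$x_km[start], f$y_km[start])
  ep <- if (is.null(f)) c(NA_real_, NA_real_) else c(f$x_km[end], f$y_km[end])
  new("MigrationWindow", startIndex = as.integer(start),
      endIndex = as.integer(end), startPoint = sp, endPoint = ep, nsd = nsd)
}

#' Summarize detected migrations across tracks
#'
#' @param tracks list of [TelemetryTrack-class].
#' @param ... passed to [detectMigration()].
#' @return data.frame with one row per track that yielded a migration:
#'   animal, season, year, start/end timestamps and coordinates, and the
#'   number of in-window fixes.  Non-migratory tracks are dropped with a
#'   message.
#' @export
migrationTable <- function(tracks, ...) {
  rows <- list()
  for (tr in tracks) {
    win <- detectMigration(tr, ...)
    if (is.null(win)) {
      message(sprintf("no migration detected: %s %s %d", tr@animalId,
                      tr@season, tr@year))
      next
    }
    fx <- tr@fixes
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = tr@animalId, season = tr@season, year = tr@year,
      start_index = win@startIndex, end_index = win@endIndex,
      start_time = fx$timestamp[win@startIndex],
      end_time = fx$timestamp[win@endIndex],
      start_x = win@startPoint[1], start_y = win@startPoint[2],
      end_x = win@endPoint[1], end_y = win@endPoint[2],
      n_fixes = win@endIndex - win@startIndex + 1L)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
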