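#' @rdname gridValues
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setGeneric("gridValues<-", function(x, value) standardGeneric("gridValues<-"))

#' @rdname gridExtent
#' @export
setGeneric("gridExtent", function(x) standardGeneric("gridExtent"))

#' @rdname cellSize
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' Fixes of a telemetry track
#' @param x a `TelemetryTrack`.
#' @return data.frame of fixes (`timestamp`, `x_km`, `y_km`).
#' @export
setGeneric("trackFixes", function(x) standardGeneric("trackFixes"))

#' @rdname effectiveResistance
#' @export
setGeneric("effectiveResistance",
           function(x) standardGeneric("effectiveResistance"))

#' @rdname currentMap
#' @export
setGeneric("currentMap", function(x) standardGeneric("currentMap"))
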