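#' @rdname sampleTypes
#' @export
setGeneric("sampleTypes", function(x) standardGeneric("sampleTypes"))

#' @rdname replicateCounts
#' @export
setGeneric("replicateCounts", function(x) standardGeneric("replicateCounts"))

#' @rdname markerCalls
#' @export
setGeneric("markerCalls", function(x) standardGeneric("markerCalls"))

#' @rdname markerList
#' @export
setGeneric("markerList", function(x) standardGeneric("markerList"))

#' @rdname plantedMarkers
#' @export
setGeneric("plantedMarkers", function(x) standardGeneric("plantedMarkers"))

#' @rdname detectMarkers
#' @export
setGeneric("detectMarkers", function(x, ...) standardGeneric("detectMarkers"))
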