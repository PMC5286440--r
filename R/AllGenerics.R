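NULL

#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' @export
setGeneric("pointKind", function(x) standardGeneric("pointKind"))

#' @export
setGeneric("suppressionRadius", function(x) standardGeneric("suppressionRadius"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setGeneric("matchCosts", function(x) standardGeneric("matchCosts"))

#' @export
setGeneric("sourcePoints", function(x) standardGeneric("sourcePoints"))

#' @export
setGeneric("targetPoints", function(x) standardGeneric("targetPoints"))

#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' @export
setGeneric("applyWarp", function(warp, pts) standardGeneric("applyWarp"))

#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))

#' @export
setGeneric("warpedSource", function(x) standardGeneric("warpedSource"))

#' @export
setGeneric("controlPairs", function(x) standardGeneric("controlPairs"))

#' @export
setGeneric("registrationMetrics", function(x) standardGeneric("registrationMetrics"))

#' @export
setGeneric("somTrace", function(x) standardGeneric("somTrace"))

#' @export
setGeneric("forwardModel", function(x) standardGeneric("forwardModel"))

#' @export
setGeneric("backwardModel", function(x) standardGeneric("backwardModel"))
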