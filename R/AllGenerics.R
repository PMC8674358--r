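#' @rdname RiddScanResult-class
#' @param x a result object.
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))

#' @rdname RiddScanResult-class
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname CleavageProfile-class
#' @param x a result object.
#' @export
setGeneric("endCounts", function(x) standardGeneric("endCounts"))

#' @rdname CleavageProfile-class
#' @export
setGeneric("nMapped", function(x) standardGeneric("nMapped"))

#' @rdname CleavageProfile-class
#' @export
setGeneric("gcFraction", function(x) standardGeneric("gcFraction"))

#' @rdname CleavageProfile-class
#' @export
setGeneric("hotspots", function(x) standardGeneric("hotspots"))
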