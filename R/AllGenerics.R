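#' @rdname StimulusProtocol-class
#' @param x a `TraceSet` or other object carrying a protocol.
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))

#' @rdname StimulusProtocol-class
#' @param value a `StimulusProtocol`.
#' @export
setGeneric("protocol<-", function(x, value) standardGeneric("protocol<-"))

#' @rdname TraceSet
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname TraceSet
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname TraceSet
#' @export
setGeneric("folds", function(x) standardGeneric("folds"))

#' @rdname TraceSet
#' @export
setGeneric("baselineF0", function(x) standardGeneric("baselineF0"))

#' @rdname TraceSet
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' @rdname TraceSet
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
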