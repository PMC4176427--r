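#' @rdname SignalSet-accessors
#' @export
setGeneric("getMeth", function(object) standardGeneric("getMeth"))

#' @rdname SignalSet-accessors
#' @export
setGeneric("getUnmeth", function(object) standardGeneric("getUnmeth"))

#' @rdname QCSummary-accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))

#' @rdname QCSummary-accessors
#' @export
setGeneric("summaryLabel", function(object) standardGeneric("summaryLabel"))

#' @rdname QCSummary-accessors
#' @export
setGeneric("summaryParams", function(object) standardGeneric("summaryParams"))

#' @rdname QCSummary-accessors
#' @export
setGeneric("quantileProbs", function(object) standardGeneric("quantileProbs"))

#' @rdname QCSummary-accessors
#' @export
setGeneric("quantileTable", function(object, stratum, measure)
    standardGeneric("quantileTable"))

#' @rdname QCSummary-accessors
#' @export
setGeneric("strataCounts", function(object) standardGeneric("strataCounts"))

#' @rdname QCSummary-accessors
#' @export
setGeneric("controlSummary", function(object) standardGeneric("controlSummary"))

#' @rdname QCSummary-accessors
#' @export
setGeneric("pcaResult", function(object) standardGeneric("pcaResult"))

#' @rdname QCSummary-accessors
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))

#' @rdname PCAResult-accessors
#' @export
setGeneric("pcaScores", function(object) standardGeneric("pcaScores"))

#' @rdname PCAResult-accessors
#' @export
setGeneric("varianceRatio", function(object) standardGeneric("varianceRatio"))

#' @rdname PCAResult-accessors
#' @export
setGeneric("selectedProbes", function(object) standardGeneric("selectedProbes"))
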