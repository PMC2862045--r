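#' @rdname RegulatoryStructure-class
#' @param x an object.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname RegulatoryStructure-class
#' @export
setGeneric("regulators", function(x) standardGeneric("regulators"))

#' @rdname RegulatoryStructure-class
#' @export
setGeneric("regulatorCoefficients",
           function(x) standardGeneric("regulatorCoefficients"))

#' @rdname RegulatoryStructure-class
#' @export
setGeneric("trueEdges", function(x) standardGeneric("trueEdges"))

#' @rdname TimeCourseExperiment
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname DirectedNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname DirectedNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname InfluenceTable-class
#' @export
setGeneric("influenceValues", function(x) standardGeneric("influenceValues"))

#' @rdname InfluenceTable-class
#' @export
setGeneric("perDelayMI", function(x) standardGeneric("perDelayMI"))

#' @rdname ThresholdResult-class
#' @export
setGeneric("thresholdI0", function(x) standardGeneric("thresholdI0"))

#' @rdname ThresholdResult-class
#' @export
setGeneric("bootstrapSamples", function(x) standardGeneric("bootstrapSamples"))

#' @rdname EvaluationResult-class
#' @export
setGeneric("evalCounts", function(x) standardGeneric("evalCounts"))

#' @rdname EvaluationResult-class
#' @export
setGeneric("evalMetrics", function(x) standardGeneric("evalMetrics"))
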