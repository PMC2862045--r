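#' @rdname RegulatoryStructure-class
#' @aliases geneIds,RegulatoryStructure-method
#' @export
setMethod("geneIds", "RegulatoryStructure", function(x) x@geneIds)

#' @rdname RegulatoryStructure-class
#' @aliases regulators,RegulatoryStructure-method
#' @export
setMethod("regulators", "RegulatoryStructure", function(x) {
    stats::setNames(x@regulators, x@geneIds)
})

#' @rdname RegulatoryStructure-class
#' @aliases regulatorCoefficients,RegulatoryStructure-method
#' @export
setMethod("regulatorCoefficients", "RegulatoryStructure", function(x) {
    stats::setNames(x@coefficients, x@geneIds)
})

#' @rdname RegulatoryStructure-class
#' @aliases trueEdges,RegulatoryStructure-method
#' @export
setMethod("trueEdges", "RegulatoryStructure", function(x) {
    n <- length(x@geneIds)
    src <- integer(0); tgt <- integer(0)
    for (i in seq_len(n)) {
        reg <- x@regulators[[i]]
        if (length(reg)) { src <- c(src, reg); tgt <- c(tgt, rep(i, length(reg))) }
    }
    data.frame(source = x@geneIds[src], target = x@geneIds[tgt],
               stringsAsFactors = FALSE)
})

setMethod("show", "RegulatoryStructure", function(object) {
    nr <- lengths(object@regulators)
    cat(sprintf("RegulatoryStructure: %d genes (%d stimulators, %d one-regulator, %d two-regulator), %d directed edges\n",
                length(object@geneIds), sum(nr == 0L), sum(nr == 1L),
                sum(nr == 2L), sum(nr)))
})

#' @rdname DirectedNetwork-class
#' @aliases networkNodes,DirectedNetwork-method
#' @param x a `DirectedNetwork`.
#' @export
setMethod("networkNodes", "DirectedNetwork", function(x) x@nodes)

#' @rdname DirectedNetwork-class
#' @aliases networkEdges,DirectedNetwork-method
#' @export
setMethod("networkEdges", "DirectedNetwork", function(x) x@edges)

setMethod("show", "DirectedNetwork", function(object) {
    cat(sprintf("DirectedNetwork: %d nodes, %d directed edges\n",
                length(object@nodes), nrow(object@edges)))
    md <- object@metadata
    if (!is.null(md$threshold))
        cat(sprintf("  threshold I0 = %.4g (mu = %.4g, sigma = %.4g, alpha = %.3g)\n",
                    thresholdI0(md$threshold), md$threshold@mu,
                    md$threshold@sigma, md$threshold@alpha))
    if (nrow(object@edges)) {
        head <- utils::head(object@edges[order(-object@edges$weight), ], 5L)
        cat("  strongest edges:\n")
        for (i in seq_len(nrow(head)))
            cat(sprintf("    %s -> %s (weight %.3f, delay %d)\n",
                        head$source[i], head$target[i],
                        head$weight[i], head$delay[i]))
    }
})

#' @rdname InfluenceTable-class
#' @aliases influenceValues,InfluenceTable-method
#' @param x an `InfluenceTable`.
#' @export
setMethod("influenceValues", "InfluenceTable", function(x) x@table)

#' @rdname InfluenceTable-class
#' @aliases perDelayMI,InfluenceTable-method
#' @export
setMethod("perDelayMI", "InfluenceTable", function(x) x@perDelay)

setMethod("show", "InfluenceTable", function(object) {
    cat(sprintf("InfluenceTable: %d ordered pairs, delays 1..%d\n",
                nrow(object@table), object@maxDelay))
})

#' @rdname ThresholdResult-class
#' @aliases thresholdI0,ThresholdResult-method
#' @param x a `ThresholdResult`.
#' @export
setMethod("thresholdI0", "ThresholdResult", function(x) x@i0)

#' @rdname ThresholdResult-class
#' @aliases bootstrapSamples,ThresholdResult-method
#' @export
setMethod("bootstrapSamples", "ThresholdResult", function(x) x@samples)

setMethod("show", "ThresholdResult", function(object) {
    cat(sprintf("ThresholdResult: I0 = %.4g (mu = %.4g, sigma = %.4g, alpha = %.3g, %d bootstrap replicates)\n",
                object@i0, object@mu, object@sigma, object@alpha, object@nBoot))
})

#' @rdname EvaluationResult-class
#' @aliases evalCounts,EvaluationResult-method
#' @param x an `EvaluationResult`.
#' @export
setMethod("evalCounts", "EvaluationResult", function(x) {
    c(tp = x@tp, fp = x@fp, fn = x@fn)
})

#' @rdname EvaluationResult-class
#' @aliases evalMetrics,EvaluationResult-method
#' @export
setMethod("evalMetrics", "EvaluationResult", function(x) {
    c(ppv = x@ppv, recall = x@recall, fscore = x@fscore)
})

setMethod("show", "EvaluationResult", function(object) {
    cat(sprintf("EvaluationResult: TP = %d, FP = %d, FN = %d | PPV = %.3f, recall = %.3f, F = %.3f\n",
                object@tp, object@fp, object@fn,
                object@ppv, object@recall, object@fscore))
})
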