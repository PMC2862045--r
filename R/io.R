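#' Network writers and readers
#'
#' `writeEdgeList()` emits a TSV with columns `source`, `target`, `weight`,
#' `delay` that round-trips through `readEdgeList()`; `writeSIF()` emits
#' Cytoscape SIF (`source regulates target`); `writeDOT()` emits Graphviz
#' DOT with weights as edge labels.
#'
#' @param network a [DirectedNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @name network-io
NULL

#' @rdname network-io
#' @export
writeEdgeList <- function(network, path) {
    utils::write.table(networkEdges(network), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname network-io
#' @param nodes optional node set; defaults to the genes seen in the edges.
#' @export
readEdgeList <- function(path, nodes = NULL) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("source", "target", "weight", "delay")
    if (!all(need %in% names(df)))
        stop("edge list must have columns: ", paste(need, collapse = ", "))
    df$source <- as.character(df$source)
    df$target <- as.character(df$target)
    df$delay <- as.integer(df$delay)
    if (is.null(nodes)) nodes <- unique(c(df$source, df$target))
    DirectedNetwork(nodes, df)
}

#' @rdname network-io
#' @export
writeSIF <- function(network, path) {
    ed <- networkEdges(network)
    writeLines(sprintf("%s\tregulates\t%s", ed$source, ed$target), path)
    invisible(path)
}

#' @rdname network-io
#' @export
writeDOT <- function(network, path) {
    ed <- networkEdges(network)
    lines <- c("digraph grn {",
               sprintf("  \"%s\";", networkNodes(network)),
               sprintf("  \"%s\" -> \"%s\" [label=\"%.3f (k=%d)\"];",
                       ed$source, ed$target, ed$weight, ed$delay),
               "}")
    writeLines(lines, path)
    invisible(path)
}

#' Serialize an InfluenceTable to TSV
#'
#' One row per ordered pair: source, target, influence, best delay and the
#' per-delay MI columns (debugging aid).
#'
#' @param x an [InfluenceTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeInfluenceTable <- function(x, path) {
    df <- cbind(influenceValues(x), as.data.frame(perDelayMI(x)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
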