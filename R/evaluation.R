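#' Harmonic-mean F-score
#'
#' `F = 2 p r / (p + r)`, with `F = 0` when `p + r = 0`. This conventional
#' harmonic form reproduces the benchmark combinations of PPV and recall
#' (e.g. p = 0.37, r = 0.60 gives F = 0.46; p = 1.0, r = 0.67 gives 0.80).
#'
#' @param p positive predictive value in `[0, 1]`.
#' @param r recall in `[0, 1]`.
#' @return F in `[0, 1]`.
#' @export
fScore <- function(p, r) {
    stopifnot(all(p >= 0 & p <= 1), all(r >= 0 & r <= 1))
    ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

## Normalize an edge specification to a two-column character data.frame.
.asEdgeDf <- function(x) {
    if (is(x, "DirectedNetwork")) x <- networkEdges(x)
    if (is(x, "RegulatoryStructure")) x <- trueEdges(x)
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    if (!all(c("source", "target") %in% names(df)))
        stop("edges need 'source' and 'target' columns")
    data.frame(source = as.character(df$source),
               target = as.character(df$target), stringsAsFactors = FALSE)
}

#' Score an inferred network against a gold standard
#'
#' Directed matching by default: a predicted edge (a, b) is a true positive
#' only if the gold standard contains (a, b) with that orientation; an edge
#' predicted with the wrong direction therefore costs one false positive
#' and one false negative. Undirected mode collapses both edge sets to
#' their skeletons first (for comparisons against networks whose edges
#' cannot carry an orientation).
#'
#' @param inferred a [DirectedNetwork-class] or edge data.frame.
#' @param truth gold-standard edges: a [RegulatoryStructure-class], a
#'   [DirectedNetwork-class], or a data.frame with `source`/`target`.
#' @param directed match directions (default `TRUE`).
#' @param truthGenes optional character vector widening the gold-standard
#'   gene universe (gold standards list only genes with edges; pass the
#'   full gene set to accept isolated genes).
#' @return an [EvaluationResult-class].
#' @export
evaluateNetwork <- function(inferred, truth, directed = TRUE,
                            truthGenes = NULL) {
    pred <- .asEdgeDf(inferred)
    gold <- .asEdgeDf(truth)
    universe <- unique(c(gold$source, gold$target, truthGenes,
                         if (is(truth, "RegulatoryStructure")) geneIds(truth)))
    unknown <- setdiff(unique(c(pred$source, pred$target)), universe)
    if (length(unknown))
        stop("inferred genes absent from the truth universe: ",
             paste(unknown, collapse = ", "))
    canon <- function(df) {
        if (directed) unique(paste(df$source, df$target, sep = "\r"))
        else unique(paste(pmin(df$source, df$target),
                          pmax(df$source, df$target), sep = "\r"))
    }
    p <- canon(pred); g <- canon(gold)
    tp <- length(intersect(p, g))
    fp <- length(p) - tp
    fn <- length(g) - tp
    ppv <- if (tp + fp) tp / (tp + fp) else 0
    rec <- if (tp + fn) tp / (tp + fn) else 0
    new("EvaluationResult", tp = as.integer(tp), fp = as.integer(fp),
        fn = as.integer(fn), ppv = ppv, recall = rec,
        fscore = fScore(ppv, rec))
}

#' Write an EvaluationResult
#'
#' JSON (counts plus metrics) or a one-line TSV row suitable for appending
#' to benchmark tables.
#'
#' @param x an [EvaluationResult-class].
#' @param path output path.
#' @param format `"json"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeEvaluation <- function(x, path, format = c("json", "tsv")) {
    format <- match.arg(format)
    if (format == "json") {
        jsonlite::write_json(as.list(c(evalCounts(x), evalMetrics(x))),
                             path, auto_unbox = TRUE, digits = NA)
    } else {
        df <- data.frame(t(c(evalCounts(x), evalMetrics(x))))
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}
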