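#' Construct a DirectedNetwork
#'
#' @param nodes character vector of gene identifiers.
#' @param edges data.frame with columns `source`, `target`, `weight`,
#'   `delay` (may have zero rows).
#' @param metadata optional list of provenance.
#' @return a validated [DirectedNetwork-class].
#' @export
DirectedNetwork <- function(nodes, edges = NULL, metadata = list()) {
    if (is.null(edges) || !nrow(edges))
        edges <- data.frame(source = character(0), target = character(0),
                            weight = numeric(0), delay = integer(0),
                            stringsAsFactors = FALSE)
    rownames(edges) <- NULL
    new("DirectedNetwork", nodes = as.character(nodes), edges = edges,
        metadata = metadata)
}

## Triangles of the skeleton (direction ignored), via igraph. Returns a
## 3-column matrix of node names.
.triangles <- function(edges, nodes) {
    if (nrow(edges) < 3L) return(matrix(character(0), 0L, 3L))
    g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                       directed = FALSE, vertices = nodes)
    g <- igraph::simplify(g)
    tri <- igraph::triangles(g)
    if (!length(tri)) return(matrix(character(0), 0L, 3L))
    matrix(igraph::V(g)$name[tri], ncol = 3L, byrow = TRUE)
}

#' Data Processing Inequality pruning
#'
#' For every triangle of the network skeleton (direction is ignored when
#' detecting triples), the connection with the smallest weight can be
#' explained as an indirect interaction and is removed — unless it lies
#' within the relative tolerance of both others (the classic
#' DPI-with-tolerance rule: prune w only when
#' `w < (1 - tolerance) * min(other two)`), so three-gene loops remain
#' possible. A connection between two nodes takes the maximum
#' weight of its directed edges; pruning a connection removes all its
#' directed edges. All triangles are judged on the input weights and
#' removals applied afterwards, which makes the operation idempotent.
#'
#' @param network a [DirectedNetwork-class] with populated weights.
#' @param tolerance relative tolerance in `[0, 1)` (default 0.15).
#' @return a [DirectedNetwork-class] whose edge set is a subset of the
#'   input's.
#' @export
applyDPI <- function(network, tolerance = 0.15) {
    stopifnot(is(network, "DirectedNetwork"))
    if (!is.numeric(tolerance) || tolerance < 0 || tolerance >= 1)
        stop("tolerance must lie in [0, 1)")
    ed <- network@edges
    if (nrow(ed) < 3L) return(network)
    key <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "\r")
    connWeight <- tapply(ed$weight, key(ed$source, ed$target), max)
    tri <- .triangles(ed, network@nodes)
    drop <- character(0)
    for (i in seq_len(nrow(tri))) {
        k <- c(key(tri[i, 1L], tri[i, 2L]),
               key(tri[i, 2L], tri[i, 3L]),
               key(tri[i, 1L], tri[i, 3L]))
        w <- connWeight[k]
        if (anyNA(w)) next  # not a full triangle among surviving connections
        lo <- which.min(w)
        if (w[lo] < (1 - tolerance) * min(w[-lo]))
            drop <- c(drop, k[lo])
    }
    if (length(drop)) {
        keep <- !(key(ed$source, ed$target) %in% drop)
        ed <- ed[keep, , drop = FALSE]
    }
    md <- network@metadata
    md$dpiRemoved <- sum(!is.na(match(key(network@edges$source,
                                         network@edges$target), drop)))
    DirectedNetwork(network@nodes, ed, md)
}

## Resolve reciprocal pairs: keep the stronger direction; keep both only
## when the two influences are within the relative tolerance of each other.
.resolveReciprocal <- function(ed, tolerance) {
    if (nrow(ed) < 2L) return(ed)
    key <- paste(pmin(ed$source, ed$target), pmax(ed$source, ed$target),
                 sep = "\r")
    keep <- rep(TRUE, nrow(ed))
    for (k in unique(key[duplicated(key)])) {
        idx <- which(key == k)
        w <- ed$weight[idx]
        if ((max(w) - min(w)) / max(w) >= tolerance)
            keep[idx[-which.max(w)]] <- FALSE
    }
    ed[keep, , drop = FALSE]
}

#' Infer a directed gene regulatory network from a time course
#'
#' The full three-step pipeline:
#' \enumerate{
#'   \item \strong{Initial change of expression.} [computeIce()] flags each
#'     gene's first significant fold change; a gene may influence only
#'     genes changing no earlier ([admissiblePairs()]).
#'   \item \strong{Network construction.} Profiles are copula-transformed
#'     and the delayed-MI influence is computed for every admissible pair
#'     over delays `1..maxDelay` ([influenceTable()]). Unless
#'     `noThreshold`, edges must exceed the stationary-bootstrap threshold
#'     I0 ([computeThreshold()]). Edges are oriented from the locked to the
#'     shifted series; if both orientations survive, the stronger is kept
#'     (both when within `dpiTolerance` of each other).
#'   \item \strong{Pruning.} The Data Processing Inequality is applied
#'     twice: first within each single-delay graph (triangles whose three
#'     edges share the same best delay), then on the final best-delay
#'     influence graph ([applyDPI()]).
#' }
#'
#' Genes with constant profiles carry no rank information and are excluded
#' with a warning; an all-constant matrix yields an empty network.
#'
#' @param x a [TimeCourseExperiment-class] or genes-by-time numeric matrix.
#' @param tauUp,tauDown fold-change thresholds of step 1 (defaults 1.2 and
#'   its reciprocal).
#' @param maxDelay largest delay K (default 3); requires `T >= maxDelay + 4`.
#' @param gridSize KDE grid cells per axis (default 100).
#' @param nBoot,alpha,meanBlockLength,pairsPerReplicate bootstrap-threshold
#'   controls, see [computeThreshold()].
#' @param dpiTolerance DPI relative tolerance (default 0.15).
#' @param noThreshold skip the bootstrap threshold and rely on DPI pruning
#'   alone (useful when signal is weak relative to the bootstrap null).
#' @param seed optional integer seed controlling the bootstrap (`NULL` =
#'   current RNG state).
#' @param verbose log threshold and pruning summaries (default `FALSE`).
#' @return a [DirectedNetwork-class]; `metadata` carries the
#'   [ThresholdResult-class] (if any), the influence table, and pruning
#'   counts.
#' @examples
#' chain <- makeChainNetwork(3, sigma2 = 0.01, nTimepoints = 50, seed = 1)
#' net <- inferNetwork(chain$expr, nBoot = 100, seed = 1)
#' networkEdges(net)
#' @export
inferNetwork <- function(x, tauUp = 1.2, tauDown = 1 / tauUp,
                         maxDelay = 3L, gridSize = 100L,
                         nBoot = 500L, alpha = 2,
                         meanBlockLength = NULL, pairsPerReplicate = 1L,
                         dpiTolerance = 0.15, noThreshold = FALSE,
                         seed = NULL, verbose = FALSE) {
    tce <- if (is(x, "TimeCourseExperiment")) x else TimeCourseExperiment(as.matrix(x))
    m <- exprValues(tce)
    maxDelay <- as.integer(maxDelay)
    if (ncol(m) < maxDelay + 4L)
        stop("too few time points: need T >= maxDelay + 4")
    if (!is.null(seed)) set.seed(seed)

    constant <- apply(m, 1L, function(p) diff(range(p)) == 0)
    if (any(constant)) {
        warning("excluding constant profile(s): ",
                paste(rownames(m)[constant], collapse = ", "))
        m <- m[!constant, , drop = FALSE]
    }
    if (nrow(m) < 2L) {
        warning("fewer than two informative genes: returning empty network")
        return(DirectedNetwork(rownames(exprValues(tce))))
    }

    ice <- computeIce(m, tauUp, tauDown)
    pairs <- suppressWarnings(admissiblePairs(ice))
    tab <- influenceTable(m, pairs, maxDelay, gridSize)
    ed <- influenceValues(tab)

    thr <- NULL
    if (!noThreshold) {
        thr <- computeThreshold(m, pairs, maxDelay, gridSize, nBoot, alpha,
                                meanBlockLength, pairsPerReplicate)
        if (verbose)
            message(sprintf("threshold I0 = %.4f (mu = %.4f, sigma = %.4f)",
                            thr@i0, thr@mu, thr@sigma))
        ed <- ed[ed$influence > thr@i0, , drop = FALSE]
    } else {
        ed <- ed[ed$influence > 0, , drop = FALSE]
    }

    ed <- data.frame(source = ed$source, target = ed$target,
                     weight = ed$influence, delay = ed$bestDelay,
                     stringsAsFactors = FALSE)
    ed <- .resolveReciprocal(ed, dpiTolerance)

    nodes <- rownames(exprValues(tce))
    md <- list(threshold = thr, influenceTable = tab,
               nEdgesBeforeDPI = nrow(ed))
    net <- DirectedNetwork(nodes, ed, md)

    ## DPI pass 1: split triangles living at a single time delay.
    removedPass1 <- 0L
    for (k in sort(unique(ed$delay))) {
        sub <- DirectedNetwork(nodes, ed[ed$delay == k, , drop = FALSE])
        pruned <- applyDPI(sub, dpiTolerance)
        gone <- nrow(networkEdges(sub)) - nrow(networkEdges(pruned))
        if (gone) {
            removedPass1 <- removedPass1 + gone
            keys <- paste(networkEdges(pruned)$source,
                          networkEdges(pruned)$target)
            ed <- ed[ed$delay != k | paste(ed$source, ed$target) %in% keys, ,
                     drop = FALSE]
        }
    }
    ## DPI pass 2: the final best-delay influence graph.
    net <- applyDPI(DirectedNetwork(nodes, ed, md), dpiTolerance)
    md <- net@metadata
    md$dpiRemovedPass1 <- removedPass1
    md$dpiRemovedPass2 <- md$dpiRemoved
    md$dpiRemoved <- NULL
    if (verbose)
        message(sprintf("DPI pruning removed %d (pass 1) + %d (pass 2) edges",
                        removedPass1, md$dpiRemovedPass2))
    DirectedNetwork(nodes, net@edges, md)
}
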