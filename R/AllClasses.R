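#' @import methods
#' @importFrom S4Vectors SimpleList metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
NULL

#' TimeCourseExperiment: an ordered gene-expression time course
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment-class]
#' holding one real-valued assay (`"expr"`, genes in rows) whose columns are
#' in strict temporal order. Validity enforces unique gene identifiers, at
#' least two time points and finite values, the minimal contract required by
#' the delayed mutual-information machinery.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#' @export
setClass("TimeCourseExperiment", contains = "SummarizedExperiment")

setValidity("TimeCourseExperiment", function(object) {
    msg <- NULL
    if (length(assays(object)) < 1L)
        return("one assay named 'expr' is required")
    m <- assay(object, 1L)
    if (!is.numeric(m))
        msg <- c(msg, "assay must be numeric")
    if (ncol(m) < 2L)
        msg <- c(msg, "at least 2 time points are required")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers (rownames) must be present and unique")
    if (is.numeric(m) && !all(is.finite(m)))
        msg <- c(msg, "expression values must all be finite")
    if (is.null(msg)) TRUE else msg
})

#' RegulatoryStructure: gold-standard topology of a simulated network
#'
#' Directed regulator sets and equation coefficients of a "well-defined"
#' network: each gene has zero (a stimulator, exogenous input), one or two
#' regulators, each regulation carrying a coefficient drawn from [0, 1] used
#' by the linear stochastic difference equations of [simulateExpression()].
#'
#' @slot geneIds character vector of unique gene identifiers.
#' @slot regulators list, per gene, of integer indices of its regulators
#'   (length 0, 1 or 2; never the gene itself).
#' @slot coefficients list, per gene, of numeric coefficients in `[0, 1]`
#'   matching the regulator count.
#' @export
setClass("RegulatoryStructure",
    representation(geneIds = "character",
                   regulators = "list",
                   coefficients = "list"))

setValidity("RegulatoryStructure", function(object) {
    n <- length(object@geneIds)
    msg <- NULL
    if (anyDuplicated(object@geneIds))
        msg <- c(msg, "gene ids must be unique")
    if (length(object@regulators) != n || length(object@coefficients) != n)
        msg <- c(msg, "regulators and coefficients must have one entry per gene")
    else {
        nr <- lengths(object@regulators)
        if (any(nr > 2L))
            msg <- c(msg, "a gene may have at most two regulators")
        if (any(nr != lengths(object@coefficients)))
            msg <- c(msg, "coefficient count must match regulator count")
        for (i in seq_len(n)) {
            reg <- object@regulators[[i]]
            if (length(reg) && (any(reg < 1L | reg > n)))
                msg <- c(msg, sprintf("regulator index out of range for gene %d", i))
            if (i %in% reg)
                msg <- c(msg, sprintf("self-regulation is not allowed (gene %d)", i))
            if (length(reg) == 2L && reg[1L] == reg[2L])
                msg <- c(msg, sprintf("duplicated regulator for gene %d", i))
        }
        cf <- unlist(object@coefficients)
        if (length(cf) && (any(!is.finite(cf)) || any(cf < 0) || any(cf > 1)))
            msg <- c(msg, "coefficients must lie in [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
})

#' InfluenceTable: delayed mutual information for every admissible pair
#'
#' For each admissible ordered gene pair (a, b): the per-delay mutual
#' information I^kappa for kappa = 1..K, the influence Infl(a, b) =
#' max_kappa I^kappa, and the maximizing delay (ties to the smallest kappa,
#' favouring direct interactions).
#'
#' @slot table data.frame with columns `source`, `target`, `influence`,
#'   `bestDelay`.
#' @slot perDelay numeric matrix, one row per pair, one column per delay.
#' @slot maxDelay integer, the largest delay K scanned.
#' @export
setClass("InfluenceTable",
    representation(table = "data.frame",
                   perDelay = "matrix",
                   maxDelay = "integer"))

setValidity("InfluenceTable", function(object) {
    tab <- object@table
    msg <- NULL
    need <- c("source", "target", "influence", "bestDelay")
    if (!all(need %in% names(tab)))
        return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
    if (nrow(tab) != nrow(object@perDelay))
        msg <- c(msg, "perDelay must have one row per pair")
    if (nrow(tab)) {
        if (any(tab$influence < 0))
            msg <- c(msg, "influence values must be non-negative")
        if (max(abs(tab$influence -
                    apply(object@perDelay, 1L, max))) > 1e-8)
            msg <- c(msg, "influence must equal the per-delay maximum")
    }
    if (is.null(msg)) TRUE else msg
})

#' ThresholdResult: stationary-bootstrap significance threshold
#'
#' The mutual-information significance threshold I0 = mu + alpha * sigma,
#' where mu and sigma are the mean and standard deviation of influence
#' values computed on stationary-bootstrap resamples of the series (the null
#' in which temporal alignment between genes is destroyed but the marginal
#' autocorrelation of each series is preserved).
#'
#' @slot i0 numeric, the threshold.
#' @slot mu,sigma numeric, moments of the bootstrap null.
#' @slot alpha numeric, the multiplier.
#' @slot nBoot integer, number of bootstrap replicates.
#' @slot samples numeric, the pooled null influence values.
#' @slot meanBlockLength numeric, expected geometric block length used.
#' @export
setClass("ThresholdResult",
    representation(i0 = "numeric", mu = "numeric", sigma = "numeric",
                   alpha = "numeric", nBoot = "integer",
                   samples = "numeric", meanBlockLength = "numeric"))

setValidity("ThresholdResult", function(object) {
    msg <- NULL
    if (object@nBoot < 1L) msg <- c(msg, "nBoot must be >= 1")
    if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
    if (abs(object@i0 - (object@mu + object@alpha * object@sigma)) > 1e-12)
        msg <- c(msg, "i0 must equal mu + alpha * sigma")
    if (is.null(msg)) TRUE else msg
})

#' DirectedNetwork: an inferred gene regulatory network
#'
#' Directed edges (source regulates target) with the influence value as
#' weight and the maximizing time delay. Inference metadata (threshold,
#' pruning counts) is carried in `metadata`.
#'
#' @slot nodes character vector of gene identifiers.
#' @slot edges data.frame with columns `source`, `target`, `weight`, `delay`.
#' @slot metadata list of inference provenance (threshold result, counts).
#' @export
setClass("DirectedNetwork",
    representation(nodes = "character",
                   edges = "data.frame",
                   metadata = "list"))

setValidity("DirectedNetwork", function(object) {
    ed <- object@edges
    msg <- NULL
    need <- c("source", "target", "weight", "delay")
    if (!all(need %in% names(ed)))
        return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
    if (nrow(ed)) {
        if (any(ed$source == ed$target))
            msg <- c(msg, "self-loops are not allowed")
        if (!all(c(ed$source, ed$target) %in% object@nodes))
            msg <- c(msg, "edge endpoints must be network nodes")
        if (any(ed$weight <= 0))
            msg <- c(msg, "edge weights must be positive")
    }
    if (is.null(msg)) TRUE else msg
})

#' EvaluationResult: directed-edge scoring against a gold standard
#'
#' True/false positive and false negative counts of predicted edges, with
#' positive predictive value p = TP/(TP+FP), recall r = TP/(TP+FN) and the
#' harmonic-mean F-score F = 2pr/(p+r).
#'
#' @slot tp,fp,fn integer counts.
#' @slot ppv,recall,fscore numeric in `[0, 1]`.
#' @export
setClass("EvaluationResult",
    representation(tp = "integer", fp = "integer", fn = "integer",
                   ppv = "numeric", recall = "numeric", fscore = "numeric"))

setValidity("EvaluationResult", function(object) {
    msg <- NULL
    if (any(c(object@tp, object@fp, object@fn) < 0L))
        msg <- c(msg, "counts must be non-negative")
    p <- if (object@tp + object@fp) object@tp / (object@tp + object@fp) else 0
    r <- if (object@tp + object@fn) object@tp / (object@tp + object@fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    if (abs(p - object@ppv) > 1e-12 || abs(r - object@recall) > 1e-12 ||
        abs(f - object@fscore) > 1e-12)
        msg <- c(msg, "metrics inconsistent with counts")
    if (is.null(msg)) TRUE else msg
})
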