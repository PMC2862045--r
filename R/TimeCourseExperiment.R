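#' Construct a TimeCourseExperiment
#'
#' Wraps a genes-by-time numeric matrix in a validated container. Columns
#' must be in temporal order; values are used as-is (no normalization is
#' applied by default, there being no universally agreed rule for expression
#' time courses).
#'
#' @param values numeric matrix, one row per gene, columns in temporal order.
#' @param geneIds character vector of unique identifiers; defaults to
#'   `rownames(values)`.
#' @param timeLabels optional ordered labels for the time points; defaults
#'   to `colnames(values)` or `t1..tT`.
#' @return a [TimeCourseExperiment-class] object.
#' @examples
#' m <- matrix(runif(20), 4, 5, dimnames = list(paste0("g", 1:4), NULL))
#' tce <- TimeCourseExperiment(m)
#' exprValues(tce)[1:2, 1:3]
#' @export
TimeCourseExperiment <- function(values, geneIds = rownames(values),
                                 timeLabels = colnames(values)) {
    values <- as.matrix(values)
    if (is.null(geneIds))
        stop("gene identifiers are required (rownames or 'geneIds')")
    if (is.null(timeLabels))
        timeLabels <- paste0("t", seq_len(ncol(values)))
    dimnames(values) <- list(as.character(geneIds), as.character(timeLabels))
    se <- SummarizedExperiment(assays = SimpleList(expr = values))
    new("TimeCourseExperiment", se)
}

#' @rdname TimeCourseExperiment
#' @aliases exprValues,TimeCourseExperiment-method
#' @param x a `TimeCourseExperiment`.
#' @export
setMethod("exprValues", "TimeCourseExperiment", function(x) assay(x, 1L))

setMethod("show", "TimeCourseExperiment", function(object) {
    cat(sprintf("TimeCourseExperiment: %d genes x %d time points\n",
                nrow(object), ncol(object)))
    callNextMethod()
})

#' Read an expression time-course matrix from delimited text
#'
#' Expects genes on rows: a first column of gene identifiers, a header row
#' of time labels, and numeric expression values. The delimiter is
#' auto-detected (tab or comma) unless given.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator; `NULL` (default) auto-detects `\t` vs `,`.
#' @return a [TimeCourseExperiment-class].
#' @export
readExpression <- function(path, sep = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) stop("parse error: '", path, "' is empty")
    if (is.null(sep))
        sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "")
    if (ncol(df) < 3L)
        stop("shape error: need a gene-id column plus >= 2 time points, got ",
             ncol(df) - 1L, " time point(s)")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("validation error: duplicated gene id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    vals <- df[, -1L, drop = FALSE]
    for (j in seq_along(vals)) {
        v <- suppressWarnings(as.numeric(vals[[j]]))
        if (anyNA(v))
            stop(sprintf("parse error: non-numeric value in column '%s', row %d",
                         names(vals)[j], which(is.na(v))[1L]))
        vals[[j]] <- v
    }
    m <- as.matrix(vals)
    rownames(m) <- ids
    TimeCourseExperiment(m, geneIds = ids, timeLabels = colnames(m))
}

#' Write an expression matrix as TSV
#'
#' Genes on rows, a header row of time labels, first column `gene`. The
#' format round-trips through [readExpression()].
#'
#' @param x a [TimeCourseExperiment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
    m <- exprValues(x)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
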