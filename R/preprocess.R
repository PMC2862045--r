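#' Rank-based empirical copula transform
#'
#' Maps a profile to fractional ranks `(rank - 0.5) / n` (ties averaged),
#' i.e. the simplest rank-based empirical copula. The output marginal is
#' uniform on its support and invariant under any strictly increasing
#' transform of the input, which makes the downstream mutual information
#' reparameterization-invariant. The half offset keeps mass away from the
#' grid borders 0 and 1, where kernel estimates are least stable.
#'
#' A constant profile carries no rank information: all values map to 0.5
#' with a warning (callers typically exclude such genes).
#'
#' @param x numeric vector, length >= 2.
#' @return numeric vector in (0, 1) of the same length.
#' @examples
#' copulaTransform(c(0.5, 0.1, 0.9))  # 0.5, 1/6, 5/6
#' @export
copulaTransform <- function(x) {
    if (length(x) < 2L) stop("need at least 2 observations")
    if (!all(is.finite(x))) stop("values must be finite")
    if (diff(range(x)) == 0) {
        warning("constant profile: copula transform is degenerate (all 0.5)")
        return(rep(0.5, length(x)))
    }
    (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Initial change of expression (IcE)
#'
#' For each gene, the first time index t >= 2 at which the expression ratio
#' to the first observation crosses the fold-change thresholds: `x_t / x_1
#' >= tauUp` (up-regulation) or `x_t / x_1 <= tauDown` (down-regulation).
#' Genes that never cross are flagged `NA` (no change). The down threshold
#' defaults to the reciprocal `1 / tauUp` so that up- and down-regulation
#' are symmetric on the ratio scale (1.2 pairs with 0.83).
#'
#' A zero first observation would make ratios undefined; such profiles are
#' shifted by a small epsilon relative to their scale, with a warning.
#'
#' @param x a [TimeCourseExperiment-class] or numeric matrix (genes x time).
#' @param tauUp up-regulation fold-change threshold, > 1 (default 1.2).
#' @param tauDown down-regulation threshold; default `1 / tauUp`.
#' @return named integer vector of first-change indices (1-based; `NA` =
#'   no change).
#' @export
computeIce <- function(x, tauUp = 1.2, tauDown = 1 / tauUp) {
    m <- if (is(x, "TimeCourseExperiment")) exprValues(x) else as.matrix(x)
    if (!is.numeric(tauUp) || tauUp <= 1)
        stop("parameter error: tauUp must be > 1")
    if (!is.numeric(tauDown) || tauDown <= 0 || tauDown >= 1)
        stop("parameter error: tauDown must lie in (0, 1)")
    ice <- rep(NA_integer_, nrow(m))
    names(ice) <- rownames(m)
    shifted <- character(0)
    for (i in seq_len(nrow(m))) {
        p <- m[i, ]
        if (p[1L] == 0) {
            eps <- max(abs(p), 1) * 1e-8
            p <- p + eps
            shifted <- c(shifted, rownames(m)[i] %||% as.character(i))
        }
        ratio <- p / p[1L]
        hit <- which(ratio[-1L] >= tauUp | ratio[-1L] <= tauDown)
        if (length(hit)) ice[i] <- hit[1L] + 1L
    }
    if (length(shifted))
        warning("zero first observation; epsilon-shifted profile(s): ",
                paste(shifted, collapse = ", "))
    ice
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Admissible ordered gene pairs under the IcE constraint
#'
#' A gene a can influence gene b only if its expression changed no later:
#' IcE(a) <= IcE(b). No-change genes (`NA`) compare as +Inf — they may be
#' regulated by anyone but can regulate only other no-change genes. If every
#' gene is flagged no-change the filter carries no information and is
#' disabled with a warning (all ordered pairs admissible), so flat data
#' degrade gracefully.
#'
#' @param ice named integer vector from [computeIce()].
#' @return data.frame with columns `source`, `target` of admissible ordered
#'   pairs (source != target).
#' @export
admissiblePairs <- function(ice) {
    ids <- names(ice)
    if (is.null(ids)) ids <- as.character(seq_along(ice))
    v <- as.numeric(ice)
    v[is.na(v)] <- Inf
    if (all(is.infinite(v)) && length(v))
        warning("all genes flagged no-change: IcE filter disabled")
    idx <- expand.grid(source = seq_along(v), target = seq_along(v))
    idx <- idx[idx$source != idx$target & v[idx$source] <= v[idx$target], ]
    data.frame(source = ids[idx$source], target = ids[idx$target],
               stringsAsFactors = FALSE)
}
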