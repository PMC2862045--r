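## Deterministic oracle fixtures used by the test suite (and handy for
## users validating an installation). Everything is generated in code from
## a seed; nothing is shipped as data.

#' Bivariate Gaussian pair with known mutual information
#'
#' Samples `n` points from a bivariate normal with correlation `rho` and
#' attaches the closed-form MI, `-0.5 * log(1 - rho^2)` nats, as the
#' expected value — the standard oracle for checking an MI estimator.
#'
#' @param rho correlation, `|rho| < 1`.
#' @param n sample size.
#' @param seed optional integer seed.
#' @return list with `x`, `y` and `expectedMI` (nats).
#' @export
makeGaussianPair <- function(rho, n, seed = NULL) {
    if (!is.numeric(rho) || abs(rho) >= 1)
        stop("parameter error: |rho| must be < 1")
    if (!is.null(seed)) set.seed(seed)
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    list(x = x, y = y, expectedMI = -0.5 * log(1 - rho^2))
}

#' Linear chain network with simulated expression
#'
#' Builds the chain g1 -> g2 -> ... -> gn (g1 a stimulator), simulates its
#' expression with [simulateExpression()] and attaches the gold-standard
#' edge list — the canonical harness for checking that direct edges are
#' recovered and the indirect g1 -> g3 shortcut is pruned by the DPI.
#'
#' @param nGenes chain length, >= 3.
#' @param coeffs regulation coefficients for genes 2..n; default all 0.9
#'   (strong regulation).
#' @param sigma2 Gaussian noise variance on the unit scale (default 0.01).
#' @param nTimepoints series length (default 50).
#' @param seed optional integer seed.
#' @param normalize passed to [simulateExpression()].
#' @return list with `expr` ([TimeCourseExperiment-class]), `structure`
#'   ([RegulatoryStructure-class]) and `truth` (edge data.frame).
#' @export
makeChainNetwork <- function(nGenes, coeffs = rep(0.9, nGenes - 1),
                             sigma2 = 0.01, nTimepoints = 50L, seed = NULL,
                             normalize = TRUE) {
    nGenes <- as.integer(nGenes)
    if (is.na(nGenes) || nGenes < 3L)
        stop("parameter error: nGenes must be >= 3")
    if (length(coeffs) != nGenes - 1L)
        stop("parameter error: need one coefficient per regulated gene")
    regs <- c(list(integer(0)), lapply(seq_len(nGenes - 1L), identity))
    cofs <- c(list(numeric(0)), as.list(as.numeric(coeffs)))
    structure <- RegulatoryStructure(sprintf("g%d", seq_len(nGenes)),
                                     regs, cofs)
    expr <- simulateExpression(structure, nTimepoints, sigma2, seed = seed,
                               normalize = normalize)
    list(expr = expr, structure = structure, truth = trueEdges(structure))
}
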