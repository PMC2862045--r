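#' Construct a RegulatoryStructure by hand
#'
#' Mostly useful for fixed test topologies (chains, fans); random benchmark
#' networks come from [generateRandomNetwork()].
#'
#' @param geneIds character vector of unique gene identifiers.
#' @param regulators list, per gene, of integer indices of regulators
#'   (0, 1 or 2 of them; self-regulation forbidden).
#' @param coefficients list, per gene, of coefficients in `[0, 1]` matching
#'   the regulator count.
#' @return a validated [RegulatoryStructure-class].
#' @export
RegulatoryStructure <- function(geneIds, regulators, coefficients) {
    new("RegulatoryStructure", geneIds = as.character(geneIds),
        regulators = lapply(regulators, as.integer),
        coefficients = lapply(coefficients, as.numeric))
}

#' Generate a random well-defined regulatory network
#'
#' Draws a random "well-defined" network: `nStimulators` genes have no
#' regulators (exogenous inputs); among the remaining genes a fraction
#' `fracOneRegulator` have one regulator and the rest have two (the
#' two-regulator count is floored, the remainder goes to one-regulator
#' genes). Regulators are sampled uniformly from the other genes, so cycles
#' may arise and are kept; self-regulation is excluded. Each regulation
#' coefficient is drawn Uniform[0, 1].
#'
#' @param nGenes number of genes, >= 3.
#' @param nStimulators number of zero-regulator genes, >= 1 and < `nGenes`;
#'   default `max(1, round(0.1 * nGenes))`.
#' @param fracOneRegulator fraction of non-stimulator genes with a single
#'   regulator (default 0.75).
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used (so callers can drive reproducibility themselves).
#' @return a [RegulatoryStructure-class].
#' @examples
#' net <- generateRandomNetwork(10, seed = 1)
#' table(lengths(regulators(net)))
#' @export
generateRandomNetwork <- function(nGenes,
                                  nStimulators = max(1L, round(0.1 * nGenes)),
                                  fracOneRegulator = 0.75,
                                  seed = NULL) {
    nGenes <- as.integer(nGenes)
    nStimulators <- as.integer(nStimulators)
    if (is.na(nGenes) || nGenes < 3L)
        stop("parameter error: nGenes must be >= 3")
    if (is.na(nStimulators) || nStimulators < 1L || nStimulators >= nGenes)
        stop("parameter error: nStimulators must be in [1, nGenes - 1]")
    if (!is.numeric(fracOneRegulator) || fracOneRegulator < 0 ||
        fracOneRegulator > 1)
        stop("parameter error: fracOneRegulator must lie in [0, 1]")
    if (!is.null(seed)) set.seed(seed)

    ids <- sprintf("g%d", seq_len(nGenes))
    stim <- sort(sample.int(nGenes, nStimulators))
    regulated <- setdiff(seq_len(nGenes), stim)
    nReg <- length(regulated)
    nTwo <- floor((1 - fracOneRegulator) * nReg)
    twoReg <- if (nTwo) sort(sample(regulated, nTwo)) else integer(0)

    regs <- vector("list", nGenes)
    cofs <- vector("list", nGenes)
    for (i in seq_len(nGenes)) {
        if (i %in% stim) {
            regs[[i]] <- integer(0); cofs[[i]] <- numeric(0)
        } else {
            k <- if (i %in% twoReg) 2L else 1L
            regs[[i]] <- sample(setdiff(seq_len(nGenes), i), k)
            cofs[[i]] <- stats::runif(k)
        }
    }
    RegulatoryStructure(ids, regs, cofs)
}

#' Simulate a time course from a regulatory structure
#'
#' Dynamics are linear first-order stochastic difference equations.
#' Stimulator profiles are i.i.d. Uniform[1, 100] (exogenous random input).
#' Each regulated gene i starts at Uniform[1, 100] and follows
#' `x_t[i] = a_i * x_{t-1}[p_i] (+ b_i * x_{t-1}[q_i]) + e_t` with
#' `e_t ~ N(0, noiseVariance * 100^2)`: the noise lives inside the
#' stochastic difference equation, so it propagates along regulatory paths
#' and indirect dependencies are noisier than direct ones. Its standard
#' deviation is expressed as a fraction of the simulation's 100-unit
#' dynamic range, which keeps variances of 0.01-0.2 consequential (the
#' whole system is equivalent to unit-scale dynamics with N(0,
#' `noiseVariance`) innovations). Every profile is finally min-max
#' normalized to `[0, 1]`.
#'
#' @param structure a [RegulatoryStructure-class].
#' @param nTimepoints number of time points T >= 2.
#' @param noiseVariance Gaussian noise variance sigma^2 >= 0 on the unit
#'   scale (default 0.02).
#' @param seed optional integer seed (`NULL` = use current RNG state).
#' @param normalize if `FALSE`, return the raw noise-free trajectories
#'   without the final unit-scale normalization; useful for verifying the
#'   recursion directly.
#' @return a [TimeCourseExperiment-class].
#' @export
simulateExpression <- function(structure, nTimepoints,
                               noiseVariance = 0.02, seed = NULL,
                               normalize = TRUE) {
    stopifnot(is(structure, "RegulatoryStructure"))
    validObject(structure)
    nTimepoints <- as.integer(nTimepoints)
    if (is.na(nTimepoints) || nTimepoints < 2L)
        stop("parameter error: nTimepoints must be >= 2")
    if (!is.numeric(noiseVariance) || is.na(noiseVariance) || noiseVariance < 0)
        stop("parameter error: noiseVariance must be >= 0")
    if (!is.null(seed)) set.seed(seed)

    n <- length(structure@geneIds)
    stim <- which(lengths(structure@regulators) == 0L)
    x <- matrix(0, n, nTimepoints)
    x[stim, ] <- stats::runif(length(stim) * nTimepoints, 1, 100)
    regulated <- setdiff(seq_len(n), stim)
    x[regulated, 1L] <- stats::runif(length(regulated), 1, 100)
    noiseSd <- sqrt(noiseVariance) * 100  # sigma as fraction of the range
    for (t in seq_len(nTimepoints)[-1L]) {
        for (i in regulated) {
            reg <- structure@regulators[[i]]
            x[i, t] <- sum(structure@coefficients[[i]] * x[reg, t - 1L]) +
                if (noiseSd > 0 && normalize) stats::rnorm(1L, sd = noiseSd) else 0
        }
    }
    if (normalize) {
        for (i in seq_len(n)) {
            rng <- range(x[i, ])
            x[i, ] <- if (diff(rng) > 0) (x[i, ] - rng[1L]) / diff(rng) else
                rep(0.5, nTimepoints)
        }
    }
    rownames(x) <- structure@geneIds
    TimeCourseExperiment(x)
}

#' Benchmark inference on random synthetic networks
#'
#' Generates `nRuns` independent random networks, simulates each, infers a
#' network and scores it against the generating structure with directed
#' matching. Metrics are computed per run and then arithmetically averaged
#' (the mean of per-run F-scores, not the F of mean PPV/recall).
#'
#' @inheritParams generateRandomNetwork
#' @inheritParams simulateExpression
#' @param nRuns number of independent networks (>= 1), default 20.
#' @param inferenceParams named list of overrides passed to
#'   [inferNetwork()] (e.g. `maxDelay`, `nBoot`, `alpha`, `dpiTolerance`).
#' @param seed integer seed governing the whole benchmark.
#' @param inferFun optional function `(tce, structure)` returning a
#'   [DirectedNetwork-class]; replaces [inferNetwork()] (used e.g. for
#'   oracle upper-bound checks). The generating structure is supplied so
#'   oracle predictors can be expressed; real predictors must ignore it.
#' @return a list with `runs` (per-run data.frame of tp/fp/fn/ppv/recall/
#'   fscore) and `summary` (mean and sd of each metric).
#' @export
runBenchmark <- function(nGenes, nTimepoints, noiseVariance = 0.02,
                         nRuns = 20L,
                         nStimulators = max(1L, round(0.1 * nGenes)),
                         fracOneRegulator = 0.75,
                         inferenceParams = list(),
                         seed = NULL, inferFun = NULL) {
    nRuns <- as.integer(nRuns)
    if (is.na(nRuns) || nRuns < 1L) stop("parameter error: nRuns must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    rows <- vector("list", nRuns)
    for (r in seq_len(nRuns)) {
        net <- generateRandomNetwork(nGenes, nStimulators, fracOneRegulator)
        tce <- simulateExpression(net, nTimepoints, noiseVariance)
        pred <- if (is.null(inferFun))
            do.call(inferNetwork, c(list(tce), inferenceParams))
        else inferFun(tce, net)
        ev <- evaluateNetwork(pred, trueEdges(net),
                              truthGenes = geneIds(net))
        rows[[r]] <- data.frame(run = r, t(evalCounts(ev)), t(evalMetrics(ev)))
    }
    runs <- do.call(rbind, rows)
    summ <- data.frame(
        metric = c("ppv", "recall", "fscore"),
        mean = c(mean(runs$ppv), mean(runs$recall), mean(runs$fscore)),
        sd = c(stats::sd(runs$ppv), stats::sd(runs$recall),
               stats::sd(runs$fscore)))
    list(runs = runs, summary = summ)
}

#' Write the gold-standard edge list of a structure
#'
#' Two-column directed edge-list TSV (`source`, `target`); optionally SIF
#' with a constant `regulates` relation.
#'
#' @param structure a [RegulatoryStructure-class].
#' @param path output path.
#' @param format `"tsv"` (default) or `"sif"`.
#' @return `path`, invisibly.
#' @export
writeGoldStandard <- function(structure, path, format = c("tsv", "sif")) {
    format <- match.arg(format)
    ed <- trueEdges(structure)
    if (format == "tsv")
        utils::write.table(ed, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    else
        writeLines(sprintf("%s\tregulates\t%s", ed$source, ed$target), path)
    invisible(path)
}
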