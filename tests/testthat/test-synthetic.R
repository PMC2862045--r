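# Random well-defined network generator and expression simulator.

test_that("regulator-count split matches the configured proportions exactly", {
  cases <- list(list(n = 20, stim = 4, frac = 0.75, one = 12, two = 4),
                list(n = 10, stim = 1, frac = 0.75, one = 7, two = 2),
                list(n = 3, stim = 1, frac = 1.0, one = 2, two = 0),
                list(n = 13, stim = 2, frac = 0.6, two = 4, one = 7))
  for (cs in cases) {
    net <- generateRandomNetwork(cs$n, cs$stim, cs$frac, seed = 42)
    nr <- lengths(regulators(net))
    expect_equal(sum(nr == 0), cs$stim)
    expect_equal(sum(nr == 1), cs$one)
    expect_equal(sum(nr == 2), cs$two)
  }
})

test_that("generated structures have no self-loops and valid coefficients", {
  for (seed in 1:5) {
    net <- generateRandomNetwork(15, seed = seed)
    regs <- regulators(net)
    for (i in seq_along(regs))
      expect_false(i %in% regs[[i]])
    cf <- unlist(regulatorCoefficients(net))
    expect_true(all(cf >= 0 & cf <= 1))
    expect_true(validObject(net))
  }
})

test_that("generation and simulation are reproducible from a seed", {
  a <- generateRandomNetwork(12, seed = 7)
  b <- generateRandomNetwork(12, seed = 7)
  expect_identical(regulators(a), regulators(b))
  expect_identical(regulatorCoefficients(a), regulatorCoefficients(b))
  x1 <- simulateExpression(a, 30, 0.05, seed = 3)
  x2 <- simulateExpression(a, 30, 0.05, seed = 3)
  expect_identical(exprValues(x1), exprValues(x2))
})

test_that("invalid generator parameters are rejected", {
  expect_error(generateRandomNetwork(2), "nGenes")
  expect_error(generateRandomNetwork(10, nStimulators = 10), "nStimulators")
  expect_error(generateRandomNetwork(10, fracOneRegulator = 1.2),
               "fracOneRegulator")
  net <- generateRandomNetwork(5, seed = 1)
  expect_error(simulateExpression(net, 10, noiseVariance = -0.1),
               "noiseVariance")
  expect_error(simulateExpression(net, 1), "nTimepoints")
})

test_that("zero-noise chain follows the linear recursion exactly", {
  ch <- makeChainNetwork(3, coeffs = c(0.6, 0.3), sigma2 = 0,
                         nTimepoints = 12, seed = 5, normalize = FALSE)
  m <- exprValues(ch$expr)
  for (t in 2:12) {
    expect_equal(m["g2", t], 0.6 * m["g1", t - 1])
    expect_equal(m["g3", t], 0.3 * m["g2", t - 1])
  }
})

test_that("normalized profiles span [0, 1] and attain both endpoints", {
  net <- generateRandomNetwork(8, seed = 2)
  m <- exprValues(simulateExpression(net, 40, noiseVariance = 0, seed = 2))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(unname(apply(m, 1, min)), rep(0, 8))
  expect_equal(unname(apply(m, 1, max)), rep(1, 8))
})

test_that("noise perturbs profiles but not the gold standard", {
  net <- generateRandomNetwork(8, seed = 3)
  clean <- simulateExpression(net, 30, 0, seed = 9)
  noisy <- simulateExpression(net, 30, 0.1, seed = 9)
  expect_false(identical(exprValues(clean), exprValues(noisy)))
  expect_identical(trueEdges(net), trueEdges(net))
  # stimulator rows share the same RNG stream position -> identical draws
  stim <- names(which(lengths(regulators(net)) == 0))
  expect_equal(exprValues(clean)[stim, ], exprValues(noisy)[stim, ])
})

test_that("one-regulator dynamics stay bounded by the stimulator range", {
  # sub-unit coefficients and bounded input: no trajectory can exceed the
  # initial/stimulator ceiling of 100 (weak-stationarity sanity check)
  for (seed in 1:3) {
    net <- generateRandomNetwork(10, fracOneRegulator = 1, seed = seed)
    raw <- exprValues(simulateExpression(net, 60, 0, seed = seed,
                                         normalize = FALSE))
    expect_true(all(raw <= 100 + 1e-9))
    expect_true(all(is.finite(raw)))
  }
})

test_that("benchmark aggregates per-run metrics", {
  oracle <- function(tce, structure) {
    ed <- trueEdges(structure)
    ed$weight <- 1; ed$delay <- 1L
    DirectedNetwork(geneIds(structure), ed)
  }
  bench <- runBenchmark(8, 20, 0.02, nRuns = 3, seed = 4, inferFun = oracle)
  expect_equal(nrow(bench$runs), 3)
  expect_equal(bench$summary$mean, c(1, 1, 1))
  expect_equal(bench$runs$fn, rep(0, 3))

  # nRuns = 1: aggregate equals the single run
  one <- runBenchmark(8, 20, 0.02, nRuns = 1, seed = 4, inferFun = oracle)
  expect_equal(one$summary$mean,
               unname(unlist(one$runs[1, c("ppv", "recall", "fscore")])))
})

test_that("gold-standard writers emit directed edge lists", {
  net <- generateRandomNetwork(6, seed = 8)
  p1 <- tempfile(fileext = ".tsv")
  writeGoldStandard(net, p1)
  ed <- utils::read.table(p1, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  expect_identical(ed, trueEdges(net))
  p2 <- tempfile(fileext = ".sif")
  writeGoldStandard(net, p2, format = "sif")
  expect_true(all(grepl("\tregulates\t", readLines(p2))))
})
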