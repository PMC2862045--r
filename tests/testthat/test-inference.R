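# DPI pruning and the end-to-end inference pipeline.

test_that("DPI removes the weak edge of an unbalanced triangle", {
  tri <- makeNet(list(list("a", "b", 1.0), list("b", "c", 0.9),
                      list("a", "c", 0.5)))
  pruned <- applyDPI(tri, 0.15)
  expect_setequal(edgeKeys(pruned), c("a b", "b c"))
})

test_that("DPI keeps triangles whose weights agree within tolerance", {
  tri <- makeNet(list(list("a", "b", 1.0), list("b", "c", 0.95),
                      list("a", "c", 0.90)))
  expect_setequal(edgeKeys(applyDPI(tri, 0.15)), edgeKeys(tri))
})

test_that("DPI leaves triangle-free graphs untouched", {
  chain <- makeNet(list(list("a", "b", 0.9), list("b", "c", 0.1),
                        list("c", "d", 0.5)))
  expect_identical(networkEdges(applyDPI(chain, 0.15)),
                   networkEdges(chain))
  empty <- DirectedNetwork(c("a", "b"))
  expect_equal(nrow(networkEdges(applyDPI(empty, 0.15))), 0)
})

test_that("DPI is idempotent and only ever removes edges", {
  set.seed(1)
  for (i in 1:8) {
    nodes <- paste0("g", 1:6)
    ed <- expand.grid(source = nodes, target = nodes,
                      stringsAsFactors = FALSE)
    ed <- ed[ed$source < ed$target, ]
    ed <- ed[sample(nrow(ed), 9), ]
    ed$weight <- runif(9, 0.1, 1)
    ed$delay <- 1L
    net <- DirectedNetwork(nodes, ed)
    once <- applyDPI(net, 0.15)
    twice <- applyDPI(once, 0.15)
    expect_true(all(edgeKeys(once) %in% edgeKeys(net)))
    expect_setequal(edgeKeys(twice), edgeKeys(once))
  }
})

test_that("inference recovers a strongly driven 3-gene chain", {
  ch <- makeChainNetwork(3, sigma2 = 0.01, nTimepoints = 50, seed = 105)
  net <- inferNetwork(ch$expr, seed = 205)
  keys <- edgeKeys(net)
  expect_true(all(c("g1 g2", "g2 g3") %in% keys))
  expect_false("g1 g3" %in% keys)
  ev <- evaluateNetwork(net, ch$truth, truthGenes = geneIds(ch$structure))
  expect_gte(evalMetrics(ev)[["recall"]], 1)
})

test_that("white-noise genes yield an empty or near-empty network", {
  set.seed(2)
  m <- matrix(runif(6 * 30), 6, 30, dimnames = list(paste0("g", 1:6), NULL))
  net <- inferNetwork(m, seed = 5)
  expect_lte(nrow(networkEdges(net)), 2)
})

test_that("removing the threshold can only add edges", {
  ch <- makeChainNetwork(4, sigma2 = 0.02, nTimepoints = 40, seed = 31)
  with_thr <- inferNetwork(ch$expr, seed = 41)
  without <- inferNetwork(ch$expr, noThreshold = TRUE, seed = 41)
  expect_true(all(edgeKeys(with_thr) %in% edgeKeys(without)))
})

test_that("edge weights exceed I0 in thresholded mode", {
  ch <- makeChainNetwork(3, sigma2 = 0.02, nTimepoints = 40, seed = 8)
  net <- inferNetwork(ch$expr, seed = 9)
  thr <- net@metadata$threshold
  expect_s4_class(thr, "ThresholdResult")
  if (nrow(networkEdges(net)))
    expect_true(all(networkEdges(net)$weight > thresholdI0(thr)))
})

test_that("inference is deterministic given a seed and row-order invariant", {
  ch <- makeChainNetwork(3, sigma2 = 0.02, nTimepoints = 40, seed = 13)
  n1 <- inferNetwork(ch$expr, seed = 99)
  n2 <- inferNetwork(ch$expr, seed = 99)
  expect_identical(networkEdges(n1), networkEdges(n2))

  perm <- exprValues(ch$expr)[c(3, 1, 2), ]
  n3 <- inferNetwork(perm, seed = 99)
  expect_setequal(edgeKeys(n3), edgeKeys(n1))
})

test_that("degenerate inputs degrade gracefully", {
  flat <- matrix(1, 4, 20, dimnames = list(paste0("g", 1:4), NULL))
  expect_warning(
    expect_warning(net <- inferNetwork(flat, seed = 1), "constant"),
    "informative")
  expect_equal(nrow(networkEdges(net)), 0)
  expect_setequal(networkNodes(net), paste0("g", 1:4))

  short <- matrix(runif(12), 2, 6, dimnames = list(c("a", "b"), NULL))
  expect_error(inferNetwork(short, maxDelay = 3), "too few time points")
})

test_that("an 11-gene, 16-point matrix runs through the pipeline", {
  # shape of a one-cycle yeast G1 subset: must produce a network, not error
  set.seed(3)
  tt <- seq(0, 2 * pi, length.out = 16)
  m <- t(sapply(1:11, function(i)
    sin(tt + i / 3) + rnorm(16, sd = 0.3) + 2))
  rownames(m) <- paste0("y", 1:11)
  net <- suppressWarnings(inferNetwork(m, nBoot = 100, seed = 7))
  expect_s4_class(net, "DirectedNetwork")
  expect_equal(length(networkNodes(net)), 11)
})
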