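# Matrix loading, copula transform, IcE and admissibility.

test_that("readExpression round-trips and validates delimited matrices", {
  fx <- writeTempExpression(11, 16, seed = 2)
  tce <- readExpression(fx$path)
  expect_s4_class(tce, "TimeCourseExperiment")
  expect_equal(dim(exprValues(tce)), c(11, 16))
  expect_equal(unname(exprValues(tce)), unname(fx$values))

  csv <- writeTempExpression(4, 5, seed = 3, sep = ",")
  expect_equal(dim(exprValues(readExpression(csv$path))), c(4, 5))
})

test_that("malformed expression files are rejected with clear errors", {
  empty <- tempfile(); file.create(empty)
  expect_error(readExpression(empty), "empty")

  dup <- tempfile()
  writeLines(c("gene\tt1\tt2", "gA\t1\t2", "gA\t3\t4"), dup)
  expect_error(readExpression(dup), "duplicated gene id")

  bad <- tempfile()
  writeLines(c("gene\tt1\tt2", "gA\t1\toops"), bad)
  expect_error(readExpression(bad), "non-numeric")

  short <- tempfile()
  writeLines(c("gene\tt1", "gA\t1", "gB\t2"), short)
  expect_error(readExpression(short), "2 time point")

  expect_error(readExpression(tempfile()), "not found")
})

test_that("copula transform gives fractional average ranks", {
  expect_equal(copulaTransform(c(0.5, 0.1, 0.9)), c(0.5, 1/6, 5/6))
  # strictly increasing input -> strictly increasing, equally spaced
  out <- copulaTransform(sort(rnorm(9)))
  expect_equal(out, ((1:9) - 0.5) / 9)
  # ties get average ranks: (1.5 - 0.5)/3 each
  expect_equal(copulaTransform(c(2, 2, 5)), c(1/3, 1/3, 5/6))
  expect_warning(res <- copulaTransform(rep(3, 5)), "constant")
  expect_equal(res, rep(0.5, 5))
})

test_that("copula transform is invariant under strictly monotone maps", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(20)
    base <- copulaTransform(x)
    expect_equal(copulaTransform(exp(x)), base)
    expect_equal(copulaTransform(2 * x + 7), base)
    expect_equal(copulaTransform(pnorm(x)), base)
  }
})

test_that("IcE finds the first ratio crossing relative to the start", {
  m <- rbind(a = c(1.0, 1.1, 1.25, 0.9),
             b = c(2, 2, 2, 2),
             c = c(10, 8, 12, 10))
  ice <- computeIce(m, tauUp = 1.2)
  expect_equal(ice[["a"]], 3)        # 1.25/1.0 crosses 1.2 first at t = 3
  expect_true(is.na(ice[["b"]]))     # constant: no change
  expect_equal(ice[["c"]], 2)        # 8/10 = 0.8 <= 1/1.2
})

test_that("tauDown defaults to the reciprocal of tauUp", {
  # down-crossing at exactly 1/1.2 must trigger under the default pairing
  m <- rbind(g = c(1.2, 1.0, 1.2, 1.2))
  expect_equal(computeIce(m, tauUp = 1.2)[["g"]], 2)
  expect_true(is.na(computeIce(m, tauUp = 1.2, tauDown = 0.5)[["g"]]))
  expect_error(computeIce(m, tauUp = 0.9), "tauUp")
  expect_error(computeIce(m, tauUp = 1.2, tauDown = 1.5), "tauDown")
})

test_that("IcE is scale invariant and epsilon-handles zero baselines", {
  set.seed(4)
  m <- matrix(runif(40, 1, 10), 4, 10,
              dimnames = list(paste0("g", 1:4), NULL))
  expect_equal(computeIce(m), computeIce(100 * m))
  z <- rbind(g0 = c(0, 0.4, 0.2, 0.1))
  expect_warning(ice <- computeIce(z), "zero first observation")
  expect_equal(ice[["g0"]], 2)
})

test_that("admissible pairs respect the IcE ordering", {
  ice <- c(A = 2L, B = 5L)
  adm <- admissiblePairs(ice)
  expect_equal(adm, data.frame(source = "A", target = "B"),
               ignore_attr = TRUE)

  tied <- admissiblePairs(c(A = 3L, B = 3L))
  expect_equal(nrow(tied), 2)  # equality admits both orientations

  # NO_CHANGE compares as +Inf: regulated by anyone, regulates only NO_CHANGE
  mix <- admissiblePairs(c(A = 2L, B = NA, C = NA))
  keys <- paste(mix$source, mix$target)
  expect_setequal(keys, c("A B", "A C", "B C", "C B"))

  expect_warning(all_na <- admissiblePairs(c(A = NA, B = NA, C = NA)),
                 "disabled")
  expect_equal(nrow(all_na), 6)  # fallback: every ordered pair
})

test_that("admissible pair count is bounded by n(n-1), equality iff all tied", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    ice <- sample(c(2:4, NA), n, replace = TRUE)
    names(ice) <- paste0("g", seq_len(n))
    adm <- suppressWarnings(admissiblePairs(ice))
    expect_lte(nrow(adm), n * (n - 1))
    if (length(unique(ice)) == 1 && !anyNA(ice))
      expect_equal(nrow(adm), n * (n - 1))
  }
})
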