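test_that("fluorescence ratio is the mean-over-mean and errors are caught", {
  expect_equal(fluorescenceRatio(c(10, 10, 10), c(10, 10, 10)), 1.0)
  expect_equal(fluorescenceRatio(c(100, 110, 90), c(10, 10, 10)), 10.0)
  r <- fluorescenceRatio(c(50, 50), c(10, 10))
  expect_equal(r, 5.0)
  expect_false(callReducer(r))  # exactly five times is not a reducer
  expect_error(fluorescenceRatio(numeric(0), c(1)), "non-empty")
  expect_error(fluorescenceRatio(c(1, 2), c(0, 0)), "> 0")
})

test_that("reducer call is strictly above-threshold and monotone", {
  expect_false(callReducer(5.0))
  expect_true(callReducer(5.0001))
  expect_false(callReducer(0))
  expect_error(callReducer(-1), ">= 0")
  ratios <- sort(runif(50, 0, 10))
  calls <- callReducer(ratios)
  expect_true(all(diff(calls) >= 0))  # monotone in the ratio
})

test_that("log2 t-test matches the closed-form Welch oracle", {
  # identical groups: perfect symmetry
  same <- log2TTest(c(4, 4, 4), c(4, 4, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$pValue, 0.5)

  set.seed(42)
  for (i in 1:50) {
    x <- rlnorm(sample(3:8, 1), 2, 0.5)
    y <- rlnorm(sample(3:8, 1), 1.5, 0.8)
    got <- log2TTest(x, y, alternative = "greater")
    want <- welchOracle(log2(x), log2(y), "greater")
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$pValue, want$pValue, tolerance = 1e-10)
    # antisymmetry: swapping groups negates t, two-sided p unchanged
    fwd <- log2TTest(x, y, alternative = "two.sided")
    rev <- log2TTest(y, x, alternative = "two.sided")
    expect_equal(fwd$statistic, -rev$statistic, tolerance = 1e-10)
    expect_equal(fwd$pValue, rev$pValue, tolerance = 1e-10)
  }

  strong <- log2TTest(c(8, 8.01, 7.99, 8.02), c(2, 2.01, 1.99, 2.02))
  expect_lt(strong$pValue, 0.01)
  expect_error(log2TTest(c(1, -1), c(1, 2)), "positive")
  expect_error(log2TTest(3, c(1, 2)), ">= 2")
})

test_that("phenotype recovery is perfect at large effect and low noise", {
  strains <- sprintf("s%02d", 1:8)
  hits <- 0L
  for (seed in 1:100) {
    fl <- generateFluorescence(strains, foldChange = 20, cv = 0.1,
                               nReps = 3, seed = seed)
    calls <- assayCalls(fl)
    if (identical(setNames(calls$isReducer, calls$strain),
                  truthReducer(fl)[calls$strain])) hits <- hits + 1L
  }
  expect_identical(hits, 100L)
})

test_that("assay calls accept a plain long-format table", {
  tab <- data.frame(
    strain = c(rep("a", 3), rep("b", 3), rep("control", 3)),
    replicate = rep(1:3, 3),
    value = c(900, 1100, 1000, 90, 110, 100, 95, 105, 100))
  calls <- assayCalls(tab)
  expect_identical(calls$isReducer, c(TRUE, FALSE))
  expect_equal(calls$ratio[calls$strain == "a"], 10, tolerance = 1e-12)
  expect_error(assayCalls(data.frame(strain = "a", value = 1)), "control")
})
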