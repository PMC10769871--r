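test_that("host subtraction removes host reads and keeps the rest", {
  set.seed(31)
  host <- Biostrings::DNAStringSet(c(host_chr = paste(
    sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")))
  hostRead <- substr(as.character(host[[1]]), 101, 200)
  randRead <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  reads <- Biostrings::DNAStringSet(c(h = hostRead, r = randRead))
  kept <- subtractHost(reads, host)
  expect_identical(names(kept), "r")
  # reverse complement of a host read is also removed (canonical k-mers)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(hostRead)))
  expect_length(subtractHost(Biostrings::DNAStringSet(c(x = rc)), host), 0)
  expect_error(subtractHost(reads, Biostrings::DNAStringSet()), "non-empty")

  # on an error-free fixture the removed fraction equals the host fraction
  mg <- generateMetagenome(2, 4000, c(0, 0), hostFraction = 0.2,
                           errorRate = 0, seed = 3)
  rd <- sampleReads(mg, "S001")
  keptF <- subtractHost(rd, hostRef(mg))
  removed <- length(rd) - length(keptF)
  expect_lt(abs(removed - 0.2 * 4000), 3 * sqrt(4000 * 0.2 * 0.8) + 1)
  # conservation and order preservation
  expect_true(all(names(keptF) %in% names(rd)))
  expect_identical(names(keptF),
                   names(rd)[names(rd) %in% names(keptF)])
})

test_that("sample QC is an inclusive one-million-read floor", {
  expect_false(qcSample(999999))
  expect_true(qcSample(1000000))
  expect_false(qcSample(0))
  expect_true(qcSample(10, minReads = 10))
})

test_that("read mapping is strand-aware, exact on clean reads", {
  mg <- generateMetagenome(2, 4000, c(0.01, 0.005), hostFraction = 0.1,
                           errorRate = 0, seed = 8)
  refs <- geneRefs(mg)
  sub <- substr(as.character(refs[[1]]), 51, 150)
  expect_identical(mapReads(Biostrings::DNAStringSet(c(a = sub)), refs), 1L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sub)))
  expect_identical(mapReads(Biostrings::DNAStringSet(c(a = rc)), refs), 1L)

  for (s in names(sampleReads(mg))) {
    truthCount <- sum(readOrigins(mg, s) == "gene")
    expect_identical(mapReads(sampleReads(mg, s), refs), truthCount)
  }
  expect_error(mapReads(sampleReads(mg, "S001"),
                        Biostrings::DNAStringSet()), "non-empty")
})

test_that("CPM arithmetic and the strict presence boundary", {
  expect_equal(computeCpm(0, 1e6), 0)
  cpm5 <- computeCpm(5, 1e6)
  expect_equal(cpm5, 5)
  expect_false(callPresence(cpm5))       # exactly 5 CPM is absent
  expect_true(callPresence(5.01))
  expect_false(callPresence(0))
  expect_equal(computeCpm(123, 2345678), 123 / 2345678 * 1e6)
  expect_error(computeCpm(5, 0), "> 0")
  expect_error(computeCpm(10, 5), "exceed")
  expect_error(callPresence(-1), ">= 0")
  # presence is monotone in mapped reads for fixed total
  cpms <- computeCpm(0:20, 1e6)
  expect_true(all(diff(callPresence(cpms, threshold = 10)) >= 0))
})

test_that("age binning is half-open, range-limited, and drops missing ages", {
  prof <- data.frame(
    sample = sprintf("s%d", 1:6),
    ageDays = c(0, 29, 30, 370, NA, 60),
    qcPass = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    present = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  bins <- binByAge(prof)
  expect_identical(bins$bin, c(0, 1))
  b0 <- bins[bins$bin == 0, ]
  expect_identical(b0$nSamples, 2L)      # ages 0 and 29 share bin 0
  expect_identical(b0$nAbsent, 1L)
  expect_equal(b0$percentAbsent, 50)
  expect_identical(bins[bins$bin == 1, "nSamples"], 1L)  # age 30 -> bin 1
  # age 370 beyond the range, NA age, and QC-failing samples are excluded
  expect_equal(sum(bins$nSamples), 3)
  expect_error(binByAge(transform(prof, ageDays = -1)), "negative")
})

test_that("prevalence test equals the closed-form 2x2 chi-square", {
  eq <- prevalenceTest(5, 100, 10, 200, correct = FALSE)
  expect_equal(eq@statistic, 0)
  expect_equal(eq@pValue, 1)

  set.seed(55)
  for (i in 1:200) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    plain <- prevalenceTest(x1, n1, x2, n2, correct = FALSE)
    want <- chisqOracle(x1, n1, x2, n2, correct = FALSE)
    expect_equal(plain@statistic, want$statistic, tolerance = 1e-10)
    expect_equal(plain@pValue, want$pValue, tolerance = 1e-10)
    yates <- prevalenceTest(x1, n1, x2, n2, correct = TRUE)
    wantY <- chisqOracle(x1, n1, x2, n2, correct = TRUE)
    expect_equal(yates@statistic, wantY$statistic, tolerance = 1e-10)
    # symmetry under group swap
    swapped <- prevalenceTest(x2, n2, x1, n1, correct = FALSE)
    expect_equal(swapped@statistic, plain@statistic, tolerance = 1e-12)
    expect_equal(swapped@pValue, plain@pValue, tolerance = 1e-12)
  }
  expect_error(prevalenceTest(5, 0, 1, 10), ">= 1")
  expect_error(prevalenceTest(11, 10, 1, 10), "\\[0, n\\]")
})

test_that("cohort rules exclude young healthy adults and split IBD", {
  prof <- data.frame(
    sample = sprintf("s%d", 1:5),
    cohort = c("healthy_adult", "healthy_adult", "ibd_uc", "ibd_cd",
               "infant"),
    ageDays = c(2 * 365, 40 * 365, NA, NA, 100),
    qcPass = TRUE, present = TRUE)
  out <- cohortFilter(prof)
  expect_false("s1" %in% out$sample)      # two-year-old healthy sample
  expect_identical(out$group[out$sample == "s3"], "UC")
  expect_identical(out$group[out$sample == "s4"], "CD")
  expect_true("s5" %in% out$sample)
  expect_identical(attr(out, "audit")$healthy_adult, 1L)
  expect_error(cohortFilter(transform(prof, cohort = "unknown")),
               "unknown cohort")
})

test_that("per-sample profiles respect the configured CPM denominator", {
  mg <- generateMetagenome(2, 3000, c(0, 2e-3), hostFraction = 0.3,
                           errorRate = 0, seed = 12)
  cfg <- bilrConfig(minReads = 100)
  filtered <- profileSamples(mg, cfg)
  expect_identical(unname(setNames(filtered$present, filtered$sample)[
    names(truthPresence(mg))]), unname(truthPresence(mg)))
  expect_equal(filtered$cpm,
               filtered$mappedReads / filtered$totalReads * 1e6)
  raw <- profileSamples(mg, bilrConfig(minReads = 100,
                                       cpmDenominator = "raw"))
  expect_equal(raw$cpm, raw$mappedReads / raw$rawReads * 1e6)
  expect_true(all(raw$cpm <= filtered$cpm))
  # conservation: host-removed + retained == input
  expect_true(all(filtered$totalReads <= filtered$rawReads))
  expect_true(all(filtered$mappedReads <= filtered$totalReads))
})
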