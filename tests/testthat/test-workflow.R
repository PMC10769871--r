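test_that("discovery workflow recovers the planted candidate end to end", {
  fix <- generatePangenome(4, 4, 40, causal = TRUE, noise = 0.04, seed = 19)
  fam <- generateBilrFamily(3, 3, 4, seed = 19)
  cfg <- bilrConfig(calibrationN = 250L, seed = 19L)
  res <- runDiscovery(fix, fam, cfg)

  # the candidate set is exactly the clustered group holding the planted
  # causal proteins
  m <- membership(res$orthogroups)
  causalCluster <- unique(m$group[m$protein %in% causalGroup(fix)])
  expect_identical(candidates(res$screen), causalCluster)

  truth <- familyTruth(fam)
  expected <- c(clade1_short = "short", clade1_long = "long",
                decoy = "none")[truth[res$calls$target]]
  expect_identical(res$calls$verdict, unname(expected))

  expect_identical(res$report$stages$proteinsIn,
                   sum(lengths(proteomes(fix))))
  expect_identical(res$report$stages$candidates, 1L)
  expect_identical(res$report$stages$bilrCalls, 6L)

  # reruns with the same seed are identical
  res2 <- runDiscovery(fix, fam, cfg)
  expect_identical(res$calls, res2$calls)
  expect_identical(candidates(res$screen), candidates(res2$screen))
  expect_identical(gumbelParams(res$profile), gumbelParams(res2$profile))
})

test_that("profiling workflow separates cohorts with known absence rates", {
  # two cohorts of 40 at true absence 50% vs 0%
  fracs <- c(rep(c(0, 4e-3), 20), rep(4e-3, 40))
  mg <- generateMetagenome(80, 2000, fracs, hostFraction = 0.1,
                           errorRate = 0.005, seed = 27,
                           cohorts = rep(c("infant", "healthy_adult"),
                                         each = 40),
                           ageDays = c(seq_len(40) * 8, rep(30 * 365, 40)))
  cfg <- bilrConfig(minReads = 500)
  res <- runProfiling(mg, cfg, correct = FALSE)
  pr <- res$profiles
  expect_identical(setNames(pr$present, pr$sample)[names(truthPresence(mg))],
                   truthPresence(mg))

  cmp <- res$prevalence[["healthy_vs_infant"]]
  expect_s4_class(cmp, "PrevalenceResult")
  want <- chisqOracle(0, 40, 20, 40, correct = FALSE)
  expect_equal(cmp@statistic, want$statistic, tolerance = 1e-10)
  expect_equal(cmp@pValue, want$pValue, tolerance = 1e-10)
  expect_lt(cmp@pValue, 0.001)

  # infant age bins tally absence among the infant cohort only
  expect_equal(sum(res$ageBins$nSamples), 40)
  expect_equal(sum(res$ageBins$nAbsent), 20)

  # rerun determinism
  res2 <- runProfiling(mg, cfg, correct = FALSE)
  expect_identical(res$profiles, res2$profiles)
})

test_that("thresholds flow from the configuration alone", {
  cfg <- bilrConfig()
  # the echoed parameters cover every threshold the stages consume
  fix <- generatePangenome(2, 2, 6, causal = TRUE, noise = 0.03, seed = 1)
  res <- runDiscovery(fix, NULL, cfg)
  echoed <- res$report$parameters
  expect_equal(echoed$fluorescenceThreshold, 5)
  expect_equal(echoed$evalueMax, 1e-100)
  expect_equal(echoed$minLengthFraction, 0.5)
  expect_identical(echoed$motif, "HGDR")
  expect_equal(echoed$cpmThreshold, 5)
  expect_equal(echoed$minReads, 1e6)
  expect_equal(echoed$ageBinWidthDays, 30)
  expect_equal(echoed$healthyMinAgeYears, 3)

  # moving a config threshold changes the corresponding call
  expect_true(callPresence(7, bilrConfig()))
  expect_false(callPresence(7, bilrConfig(cpmThreshold = 10)))
  expect_false(callReducer(4, bilrConfig()@fluorescenceThreshold))
  expect_true(callReducer(4, bilrConfig(fluorescenceThreshold = 3)@
                               fluorescenceThreshold))
})

test_that("run reports serialize as JSON", {
  fix <- generatePangenome(2, 2, 6, causal = TRUE, noise = 0.03, seed = 1)
  res <- runDiscovery(fix, NULL, bilrConfig())
  f <- withr::local_tempfile(fileext = ".json")
  writeRunReport(res$report, f)
  back <- jsonlite::read_json(f)
  expect_identical(back$workflow, "discovery")
  expect_identical(back$stages$candidates, res$report$stages$candidates)
  expect_equal(back$parameters$evalueMax, 1e-100)
})
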