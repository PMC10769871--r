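test_that("planted causal orthogroup tracks the phenotype exactly", {
  fix <- generatePangenome(5, 5, 200, causal = TRUE, noise = 0.05, seed = 7)
  ids <- unlist(lapply(proteomes(fix), names), use.names = FALSE)
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(lengths(proteomes(fix)) >= 1))

  strainOf <- rep(names(proteomes(fix)), lengths(proteomes(fix)))
  names(strainOf) <- ids
  causalStrains <- sort(unique(strainOf[causalGroup(fix)]))
  reducers <- sort(names(phenotype(fix))[phenotype(fix) == "reducer"])
  expect_identical(causalStrains, reducers)
  # causal members are EC class 1 annotated
  expect_true(all(startsWith(ecTable(fix)[causalGroup(fix)], "1")))
})

test_that("pangenome generation is deterministic and arguments validated", {
  a <- generatePangenome(2, 2, 20, causal = TRUE, noise = 0.05, seed = 11)
  b <- generatePangenome(2, 2, 20, causal = TRUE, noise = 0.05, seed = 11)
  expect_identical(lapply(proteomes(a), as.character),
                   lapply(proteomes(b), as.character))
  expect_identical(ecTable(a), ecTable(b))
  expect_identical(groupTruth(a), groupTruth(b))

  noCausal <- generatePangenome(1, 1, 2, causal = FALSE, noise = 0, seed = 1)
  expect_length(causalGroup(noCausal), 0)

  expect_error(generatePangenome(0, 5, 10, TRUE, 0.05, 1), "strain")
  expect_error(generatePangenome(5, 5, 1, TRUE, 0.05, 1), "nGroups")
  expect_error(generatePangenome(5, 5, 10, TRUE, 0.5, 1), "noise")
})

test_that("bilr family fixture carries motif/domain/length truth", {
  fam <- generateBilrFamily(5, 5, 10, seed = 3)
  expect_length(sequences(fam), 20)
  tr <- familyTruth(fam)
  clade1 <- names(tr)[tr != "decoy"]
  expect_true(all(motifTruth(fam)[clade1] == "HGDR"))
  # every clade-1 core spells HGDR at the recorded motif positions
  ms <- fam@motifStart
  expect_true(all(substr(as.character(sequences(fam)[clade1]),
                         ms, ms + 3) == "HGDR"))
  expect_identical(unname(domainTable(fam)[["long01"]]),
                   c("PF07992", "PF00724"))
  expect_identical(unname(domainTable(fam)[["short01"]]), "PF00724")

  dt <- decoyType(fam)
  motifDecoys <- names(dt)[dt == "motif"]
  expect_true(all(motifTruth(fam)[motifDecoys] != "HGDR"))
  lenDecoys <- names(dt)[dt == "length"]
  refLen <- nchar(as.character(sequences(fam)[[fam@referenceId]]))
  expect_true(all(nchar(as.character(sequences(fam)[lenDecoys])) <
                  0.5 * refLen))

  expect_error(generateBilrFamily(1, 0, 3, seed = 1), "clade-1")
  expect_error(generateBilrFamily(0, 0, 0, seed = 1))

  again <- generateBilrFamily(5, 5, 10, seed = 3)
  expect_identical(as.character(sequences(fam)),
                   as.character(sequences(again)))
})

test_that("metagenome fixture honours origin fractions and truth", {
  mg <- generateMetagenome(3, 5000, c(0, 1e-3, 0.01), hostFraction = 0.2,
                           errorRate = 0, seed = 9)
  expect_identical(unname(truthPresence(mg)), c(FALSE, TRUE, TRUE))
  expect_identical(as.integer(table(readOrigins(mg, "S001"))[["gene"]]), 0L)

  # per-origin counts are deterministic rounds of fraction * reads, hence
  # within any binomial tolerance of expectation
  for (s in names(sampleReads(mg))) {
    f <- truthGeneFraction(mg)[s]
    obs <- sum(readOrigins(mg, s) == "gene")
    expect_equal(obs, unname(round(f * 5000)))
    expect_lt(abs(obs - f * 5000), 3 * sqrt(5000 * f * (1 - f)) + 1)
  }
  expect_true(all(Biostrings::width(sampleReads(mg, "S002")) == 100L))

  # an error-free read copied from a gene reference maps
  gr <- sampleReads(mg, "S003")[readOrigins(mg, "S003") == "gene"][1]
  expect_identical(mapReads(gr, geneRefs(mg), bilrConfig()), 1L)

  expect_error(generateMetagenome(3, 100, c(0, 1), seed = 1),
               "one entry per sample")
  expect_error(generateMetagenome(1, 100, 0.9, hostFraction = 0.2, seed = 1),
               "<= 1")

  again <- generateMetagenome(3, 5000, c(0, 1e-3, 0.01), hostFraction = 0.2,
                              errorRate = 0, seed = 9)
  expect_identical(as.character(sampleReads(mg, "S002")),
                   as.character(sampleReads(again, "S002")))
})

test_that("fluorescence fixture plants the requested effect size", {
  fl <- generateFluorescence(sprintf("s%d", 1:6), foldChange = 20,
                             cv = 0.05, nReps = 3, seed = 2)
  expect_true(all(lengths(measurements(fl)) == 3))
  expect_true(all(controlValues(fl) > 0))
  calls <- assayCalls(fl)
  expect_identical(setNames(calls$isReducer, calls$strain),
                   truthReducer(fl)[calls$strain])

  flat <- generateFluorescence(c("x", "y"), foldChange = 1, cv = 0.05,
                               nReps = 3, seed = 4)
  cf <- assayCalls(flat)
  expect_true(all(abs(cf$ratio - 1) < 0.5))
  expect_false(any(cf$isReducer))

  expect_error(generateFluorescence("x", foldChange = 0, seed = 1),
               "foldChange")
  expect_error(generateFluorescence("x", nReps = 2, seed = 1), "nReps")
  a <- generateFluorescence(c("x", "y"), seed = 5)
  b <- generateFluorescence(c("x", "y"), seed = 5)
  expect_identical(measurements(a), measurements(b))
})
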