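makeMsa <- function(x) Biostrings::AAStringSet(x)

test_that("profile construction follows the reference span and Laplace rule", {
  # five identical ungapped sequences: every column is a match column
  s <- randomAASeq(40)
  msa <- makeMsa(setNames(rep(s, 5), paste0("m", 1:5)))
  p <- buildProfile(msa, "m1", motifReferencePositions = 10:13)
  expect_identical(nMatchColumns(p), 40L)
  expect_identical(referenceLength(p), 40L)

  # restricting to a 1..20 span of a longer reference keeps 20 columns
  p2 <- buildProfile(msa, "m1", motifReferencePositions = 10:13,
                     referenceSpan = c(1, 20))
  expect_identical(nMatchColumns(p2), 20L)
  expect_identical(referenceLength(p2), 40L)  # full protein length

  # Laplace estimate: counts {A:4, C:1} + 1 pseudocount over 20 letters
  col <- c("A", "A", "A", "A", "C")
  msa2 <- makeMsa(setNames(paste0(col, "DDDD"), paste0("x", 1:5)))
  p3 <- buildProfile(msa2, "x1", motifReferencePositions = 2:5)
  expect_equal(unname(matchEmissions(p3)[1, "A"]), 5 / 25)
  expect_equal(unname(matchEmissions(p3)[1, "C"]), 2 / 25)
  expect_equal(unname(matchEmissions(p3)[1, "W"]), 1 / 25)

  # a motif position in a gap-demoted column is a build error
  gappy <- makeMsa(c(r = "ACDEF", a = "A-DEF", b = "A-DEF", c = "A-DEF"))
  expect_error(buildProfile(gappy, "r", motifReferencePositions = 1:4),
               "non-match column")
})

test_that("local Viterbi aligns the consensus cleanly and is local", {
  fam <- generateBilrFamily(3, 2, 0, seed = 6, coreLength = 60,
                            extLength = 20, motifStart = 20)
  p <- familyProfile(fam, spanLength = 60)
  cons <- apply(matchEmissions(p), 1, function(r) names(which.max(r)))
  consensus <- paste(cons, collapse = "")
  hit <- viterbiSearch(p, consensus)
  expect_true(all(matchMap(hit) > 0))           # no deletions
  expect_identical(hitRegion(hit), c(1L, 60L))  # full span aligned

  # embedding in unrelated flanks never lowers the score
  set.seed(8)
  flanked <- paste0(randomAASeq(15), consensus, randomAASeq(15))
  expect_gte(viterbiSearch(p, flanked)@score, hit@score)
  expect_error(viterbiSearch(p, ""), "empty")
})

test_that("Viterbi equals exhaustive path enumeration on small instances", {
  set.seed(33)
  for (i in 1:60) {
    L <- sample(2:5, 1)
    p <- randomProfile(L, seed = 1000 + i)
    target <- sample.int(20, sample(1:6, 1), replace = TRUE)
    em <- log2(sweep(matchEmissions(p), 2, p@background, "/"))
    got <- viterbiSearch(p, paste(aaAlphabet()[target], collapse = ""))
    want <- viterbiOracle(em, p@transitions, target)
    expect_equal(got@score, want, tolerance = 1e-9)
  }
})

test_that("Gumbel calibration recovers parameters and is deterministic", {
  set.seed(19)
  draws <- rgumbel(5000, mu = 2, lambda = 0.7)
  fit <- fitGumbel(draws)
  expect_lt(abs(fit["mu"] - 2), 0.1)
  expect_lt(abs(fit["lambda"] - 0.7), 0.05)
  expect_error(fitGumbel(rep(3, 100)), "degenerate")

  fam <- generateBilrFamily(3, 2, 0, seed = 6, coreLength = 60,
                            extLength = 20, motifStart = 20)
  p <- familyProfile(fam, spanLength = 60)
  c1 <- calibrate(p, nRandom = 250, randomLength = 80, seed = 5)
  c2 <- calibrate(p, nRandom = 250, randomLength = 80, seed = 5)
  expect_identical(gumbelParams(c1), gumbelParams(c2))
  expect_error(calibrate(p, nRandom = 100, seed = 1), ">= 200")
})

test_that("E-values follow the Gumbel tail and database scaling", {
  p <- randomProfile(3, seed = 2)
  p@mu <- 2; p@lambda <- 0.7
  expect_equal(scoreToEvalue(2, p, 1), 1 - exp(-1))
  expect_equal(scoreToEvalue(4, p, 200), 100 * 2 * scoreToEvalue(4, p, 1))
  s <- seq(0, 20, by = 0.5)
  expect_true(all(diff(scoreToEvalue(s, p, 10)) < 0))
  expect_error(scoreToEvalue(1, randomProfile(3, 1), 10), "not calibrated")
})

test_that("classifier recovers family truth with per-filter audits", {
  fam <- generateBilrFamily(5, 5, 10, seed = 3)
  prof <- calibrate(familyProfile(fam), nRandom = 300, randomLength = 150,
                    seed = 7)
  calls <- classifyDatabase(prof, sequences(fam), domainTable(fam))
  truth <- familyTruth(fam)
  expected <- c(clade1_short = "short", clade1_long = "long",
                decoy = "none")[truth[calls$target]]
  expect_identical(calls$verdict, unname(expected))
  # every decoy's audit names its planted violation
  dt <- decoyType(fam)
  for (d in names(dt)) {
    row <- calls[calls$target == d, ]
    flag <- switch(dt[[d]], motif = row$motifPass, length = row$lengthPass,
                   domain = row$domainPass, evalue = row$evaluePass)
    expect_false(flag)
  }
})

test_that("classification is order-invariant over the target database", {
  fam <- generateBilrFamily(3, 3, 4, seed = 14)
  prof <- calibrate(familyProfile(fam), nRandom = 250, randomLength = 120,
                    seed = 2)
  fwd <- classifyDatabase(prof, sequences(fam), domainTable(fam))
  revd <- classifyDatabase(prof, rev(sequences(fam)), domainTable(fam))
  revd <- revd[match(fwd$target, revd$target), ]
  rownames(revd) <- NULL
  expect_identical(fwd, revd)
})

test_that("motif detection is by column homology, and boundaries are strict", {
  fam <- generateBilrFamily(4, 4, 0, seed = 10)
  prof <- calibrate(familyProfile(fam), nRandom = 250, randomLength = 150,
                    seed = 4)
  tg <- as.character(sequences(fam)[["long02"]])
  hit <- viterbiSearch(prof, tg, id = "long02")
  ok <- classifyBilr(hit, tg, c("PF07992", "PF00724"), prof)
  expect_identical(verdict(ok), "long")
  expect_identical(ok@motifObserved, "HGDR")

  # the mutant DR -> AA at motif positions 3-4 must be rejected
  ms <- fam@motifStart
  mut <- tg
  substr(mut, ms + 2, ms + 3) <- "AA"
  mhit <- viterbiSearch(prof, mut, id = "mut")
  bad <- classifyBilr(mhit, mut, c("PF07992", "PF00724"), prof)
  expect_identical(verdict(bad), "none")
  expect_false(filterAudit(bad)[["motif_pass"]])
  expect_identical(bad@motifObserved, "HGAA")
  # ... even though a regex search elsewhere could be fooled: plant an
  # HGDR substring outside the motif columns
  planted <- paste0("HGDR", mut)
  phit <- viterbiSearch(prof, planted, id = "planted")
  pcall <- classifyBilr(phit, planted, c("PF07992", "PF00724"), prof)
  expect_false(filterAudit(pcall)[["motif_pass"]])

  # length boundary: 0.49x the reference length fails, 0.5x passes
  refLen <- referenceLength(prof)
  shortSeq <- substr(tg, 1, floor(0.49 * refLen))
  shit <- viterbiSearch(prof, shortSeq, id = "s")
  scall <- classifyBilr(shit, shortSeq, "PF00724", prof)
  expect_false(filterAudit(scall)[["length_pass"]])

  # domain architecture: duplicates collapse, extra domains fail
  dup <- classifyBilr(hit, tg, c("PF00724", "PF00724", "PF01266"), prof)
  expect_false(filterAudit(dup)[["domain_pass"]])
  expect_identical(dup@domainReason, "unexpected_set")
  una <- classifyBilr(hit, tg, NULL, prof)
  expect_false(filterAudit(una)[["domain_pass"]])
  expect_identical(una@domainReason, "unannotated")
})

test_that("weakening thresholds never shrinks the accepted set", {
  fam <- generateBilrFamily(4, 4, 8, seed = 12)
  prof <- calibrate(familyProfile(fam), nRandom = 250, randomLength = 150,
                    seed = 3)
  strict <- classifyDatabase(prof, sequences(fam), domainTable(fam))
  loose <- classifyDatabase(prof, sequences(fam), domainTable(fam),
                            evalueMax = 1e-10, minLengthFraction = 0.3)
  strictSet <- strict$target[strict$verdict != "none"]
  looseSet <- loose$target[loose$verdict != "none"]
  expect_true(all(strictSet %in% looseSet))
})

test_that("profiles serialize to JSON and back exactly", {
  fam <- generateBilrFamily(3, 2, 0, seed = 6, coreLength = 60,
                            extLength = 20, motifStart = 20)
  p <- calibrate(familyProfile(fam, spanLength = 60), nRandom = 250,
                 randomLength = 80, seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  writeProfileHMM(p, f)
  q <- readProfileHMM(f)
  expect_equal(matchEmissions(q), matchEmissions(p))
  expect_identical(motifColumns(q), motifColumns(p))
  expect_identical(referenceLength(q), referenceLength(p))
  expect_equal(gumbelParams(q), gumbelParams(p))
  expect_equal(q@transitions, p@transitions)
})
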