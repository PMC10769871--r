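test_that("alignment scores match the textbook affine-gap DP oracle", {
  s <- "ACDEFGHIK"
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- get("BLOSUM62", envir = e)
  selfExpected <- sum(diag(B62)[strsplit(s, "")[[1]]])
  expect_equal(alignScore(s, s), selfExpected)
  expect_gt(alignScore(s, s),
            alignScore(s, paste(rev(strsplit(s, "")[[1]]), collapse = "")))

  set.seed(7)
  for (i in 1:50) {
    a <- randomAASeq(sample(5:40, 1))
    b <- randomAASeq(sample(5:40, 1))
    expect_equal(alignScore(a, b), swOracle(a, b), tolerance = 1e-9)
    expect_equal(alignScore(a, b), alignScore(b, a))  # symmetric
  }
  expect_error(alignScore("ACXB", "ACD"), "unknown residue")
})

test_that("reciprocal-best-hit clustering recovers gene families", {
  set.seed(21)
  shared <- randomAASeq(80)
  prot <- list(
    s1 = Biostrings::AAStringSet(c(s1_a = shared, s1_b = randomAASeq(60))),
    s2 = Biostrings::AAStringSet(c(s2_a = shared, s2_b = randomAASeq(60))),
    s3 = Biostrings::AAStringSet(c(s3_a = shared, s3_b = randomAASeq(60))))
  og <- clusterOrthogroups(prot)
  m <- membership(og)
  # the shared protein forms one cross-strain group ...
  gShared <- unique(m$group[m$protein %in% c("s1_a", "s2_a", "s3_a")])
  expect_length(gShared, 1)
  # ... and the unrelated proteins are singletons
  for (p in c("s1_b", "s2_b", "s3_b"))
    expect_length(groupMembers(og, m$group[m$protein == p]), 1)
  # orthogroups partition the universe
  expect_setequal(m$protein, unlist(lapply(prot, names)))
  expect_false(anyDuplicated(m$protein) > 0)
})

test_that("clustering recovers planted fixture families exactly", {
  fix <- generatePangenome(3, 3, 30, causal = TRUE, noise = 0.05, seed = 5)
  og <- clusterOrthogroups(fix)
  truth <- groupTruth(fix)
  m <- membership(og)
  found <- setNames(m$group, m$protein)[names(truth)]
  # same partition: the map truth-group -> found-group is a bijection
  tab <- table(truth, found)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("clustering is invariant to strain and protein input order", {
  fix <- generatePangenome(2, 2, 12, causal = TRUE, noise = 0.04, seed = 13)
  prot <- proteomes(fix)
  og1 <- clusterOrthogroups(prot)
  shuffled <- rev(lapply(prot, function(x) rev(x)))
  og2 <- clusterOrthogroups(shuffled)
  m1 <- membership(og1); m2 <- membership(og2)
  key <- function(m) {
    sets <- split(m$protein, m$group)
    sort(vapply(sets, function(s) paste(sort(s), collapse = "+"),
                character(1)))
  }
  expect_identical(key(m1), key(m2))
})

test_that("oxidoreductase filter counts class-1 members by EC prefix", {
  m <- data.frame(
    protein = sprintf("p%d", 1:10),
    strain = rep(c("a", "b"), 5),
    group = rep(c("g1", "g2", "g3"), c(3, 2, 5)))
  og <- bilRscreen:::makeOrthogroupSet(m)
  ec <- c(p1 = "1.3.1.34", p2 = "1.3.1.34", p3 = "1.3.1.34",  # g1: 3 hits
          p4 = "1.3.1.34", p5 = "1.3.1.34",                    # g2: 2 hits
          p6 = "1.17.1.2", p7 = "1.17.1.2", p8 = "1.17.1.2",   # g3: 3 hits
          p9 = "2.7.1.1")                                      # + other class
  kept <- filterOxidoreductase(og, ec)
  expect_setequal(groupIds(kept), c("g1", "g3"))  # g2 has only 2
  # stricter all-members reading drops g3 (one member class 2, one missing)
  keptAll <- filterOxidoreductase(og, ec, allMembers = TRUE)
  expect_setequal(groupIds(keptAll), "g1")
  expect_warning(filterOxidoreductase(og, c(p1 = "oxido?")), "malformed")
})

test_that("phenotype pattern screen finds exactly the planted group", {
  fix <- generatePangenome(5, 5, 50, causal = TRUE, noise = 0.03, seed = 17)
  og <- trueOrthogroups(fix)
  res <- phenotypePatternScreen(og, phenotype(fix))
  causalId <- unique(groupTruth(fix)[causalGroup(fix)])
  expect_true(causalId %in% candidates(res))
  # a group present everywhere is never a candidate
  everywhere <- groupIds(og)[rowSums(presenceMatrix(og)) ==
                             ncol(presenceMatrix(og))]
  expect_false(any(everywhere %in% candidates(res)))
  # scored mode: the Hamming-0 set equals the strict candidate set
  sc <- phenotypePatternScreen(og, phenotype(fix), mode = "scored")
  expect_setequal(candidates(sc), candidates(res))
  expect_true(all(diff(screenAudit(sc)$hamming) >= 0))

  expect_error(phenotypePatternScreen(og, setNames(rep("reducer", 10),
                                                   names(phenotype(fix)))),
               "non-reducer")
  expect_error(phenotypePatternScreen(og, phenotype(fix)[-1]), "missing")
})

test_that("EC filter and pattern screen commute", {
  fix <- generatePangenome(4, 4, 40, causal = TRUE, noise = 0.03, seed = 23)
  og <- trueOrthogroups(fix)
  ec <- ecTable(fix)
  ph <- phenotype(fix)
  # EC filter then pattern
  a <- candidates(phenotypePatternScreen(filterOxidoreductase(og, ec), ph))
  # pattern then EC filter
  patt <- candidates(phenotypePatternScreen(og, ph))
  b <- intersect(patt, groupIds(filterOxidoreductase(og, ec)))
  expect_setequal(a, b)
  expect_setequal(candidates(screenCandidates(og, ec, ph)), a)
})
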