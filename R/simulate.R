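#' @include AllClasses.R
NULL

# i.i.d. substitutions at `rate`; positions in `protect` are never touched
mutateAA <- function(seq, rate, protect = integer(0)) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  hit <- setdiff(hit, protect)
  if (length(hit)) {
    repl <- sample(AA_STANDARD, length(hit), replace = TRUE)
    same <- repl == ch[hit]
    while (any(same)) {   # substitutions change the residue
      repl[same] <- sample(AA_STANDARD, sum(same), replace = TRUE)
      same <- repl == ch[hit]
    }
    ch[hit] <- repl
  }
  paste(ch, collapse = "")
}

# a short deletion or insertion, for background (non-causal) families only
applyIndel <- function(seq) {
  n <- nchar(seq)
  len <- sample(1:8, 1)
  if (runif(1) < 0.5 && n > len + 10) {
    at <- sample(n - len, 1)
    paste0(substr(seq, 1, at - 1), substr(seq, at + len, n))
  } else {
    at <- sample(n, 1)
    paste0(substr(seq, 1, at), paste(sample(AA_STANDARD, len, TRUE),
                                     collapse = ""), substr(seq, at + 1, n))
  }
}

#' Simulate a pangenome with a planted phenotype-causal orthogroup
#'
#' Emulates the comparative-genomics input of the discovery screen: a small
#' panel of bilirubin-reducer and non-reducer strains, each orthogroup
#' derived from a random ancestral protein by i.i.d. substitutions at rate
#' `noise` (plus occasional short indels in background families; the causal
#' family core is indel-free so motif positions stay addressable).
#' Background groups are present in each strain independently with
#' probability `pPresence`, so the chance that a background group
#' accidentally matches the phenotype pattern is
#' `pPresence^R * (1 - pPresence)^N`. When `causal` is TRUE exactly one
#' group is planted whose presence tracks the phenotype exactly and whose
#' members carry a class-1 ("1.-.-.-") EC label. A small fraction of
#' background families (default 6%, the rough oxidoreductase share of a
#' bacterial proteome's annotated orthogroups) is annotated with class-1 EC
#' numbers; a larger fraction carries other EC classes; the rest are
#' unannotated.
#'
#' @param nReducers,nNonreducers strain counts (>= 1 each).
#' @param nGroups total number of orthogroups (>= 2).
#' @param causal plant a causal group tracking the phenotype?
#' @param noise per-residue substitution rate in `[0, 0.3)`.
#' @param seed RNG seed; fixtures are byte-identical for a fixed seed.
#' @param pPresence background per-strain presence probability.
#' @param pOxidoFamily fraction of background families annotated as
#'   oxidoreductases (EC class 1).
#' @param pOtherEcFamily fraction of background families annotated with a
#'   non-class-1 EC.
#' @param causalLength,lengthRange protein lengths (residues).
#' @return a [PangenomeFixture-class].
#' @examples
#' fix <- generatePangenome(2, 2, 10, causal = TRUE, noise = 0.05, seed = 1)
#' fix
#' @export
generatePangenome <- function(nReducers, nNonreducers, nGroups, causal,
                              noise, seed, pPresence = 0.7,
                              pOxidoFamily = 0.06, pOtherEcFamily = 0.45,
                              causalLength = 400L,
                              lengthRange = c(120L, 250L)) {
  if (nReducers < 1 || nNonreducers < 1) stop("need >= 1 strain per phenotype")
  if (nGroups < 2) stop("'nGroups' must be >= 2")
  if (noise < 0 || noise >= 0.3) stop("'noise' must be in [0, 0.3)")
  withSeed(seed, {
    strains <- c(sprintf("R%02d", seq_len(nReducers)),
                 sprintf("N%02d", seq_len(nNonreducers)))
    pheno <- setNames(rep(c("reducer", "non_reducer"),
                          c(nReducers, nNonreducers)), strains)
    nStr <- length(strains)
    causalIdx <- if (causal) 1L else 0L
    groups <- sprintf("OG%04d", seq_len(nGroups))

    presence <- matrix(runif(nGroups * nStr) < pPresence, nGroups, nStr,
                       dimnames = list(groups, strains))
    ecClass1 <- c("1.1.1.1", "1.3.1.34", "1.6.99.1", "1.17.7.4")
    ecOther <- c("2.7.1.1", "3.2.1.4", "4.2.1.2", "5.3.1.9", "6.3.2.1")
    famKind <- sample(c("oxido", "other", "none"), nGroups, replace = TRUE,
                      prob = c(pOxidoFamily, pOtherEcFamily,
                               1 - pOxidoFamily - pOtherEcFamily))
    if (causal) {
      presence[1L, ] <- pheno[strains] == "reducer"
      famKind[1L] <- "causal"
    }
    lens <- sample(lengthRange[1]:lengthRange[2], nGroups, replace = TRUE)
    if (causal) lens[1L] <- causalLength
    ancestors <- vapply(lens, function(l)
      paste(sample(AA_STANDARD, l, replace = TRUE), collapse = ""),
      character(1))

    seqs <- vector("list", nStr)
    names(seqs) <- strains
    for (s in strains) seqs[[s]] <- character(0)
    groupOf <- lapply(strains, function(s) character(0))
    names(groupOf) <- strains
    for (g in seq_len(nGroups)) {
      for (s in strains[presence[g, ]]) {
        m <- mutateAA(ancestors[g], noise)
        if (g != causalIdx && runif(1) < 0.15) m <- applyIndel(m)
        seqs[[s]] <- c(seqs[[s]], m)
        groupOf[[s]] <- c(groupOf[[s]], groups[g])
      }
    }
    # a strain left empty by the Bernoulli draws still needs a protein
    for (s in strains) {
      if (!length(seqs[[s]])) {
        seqs[[s]] <- paste(sample(AA_STANDARD, 150, TRUE), collapse = "")
        groupOf[[s]] <- paste0("OGS_", s)
      }
    }

    proteomes <- list()
    groupTruth <- character(0)
    ecTable <- character(0)
    causalMembers <- character(0)
    for (s in strains) {
      ids <- sprintf("%s_p%04d", s, seq_along(seqs[[s]]))
      aas <- Biostrings::AAStringSet(setNames(seqs[[s]], ids))
      proteomes[[s]] <- aas
      groupTruth[ids] <- groupOf[[s]]
    }
    allIds <- names(groupTruth)
    for (g in seq_len(nGroups)) {
      members <- allIds[groupTruth == groups[g]]
      kind <- famKind[g]
      if (kind == "causal") {
        ecTable[members] <- "1.-.-.-"
        causalMembers <- members
      } else if (kind == "oxido") {
        lab <- sample(ecClass1, 1)
        ann <- members[runif(length(members)) < 0.9]
        if (length(ann)) ecTable[ann] <- lab
      } else if (kind == "other") {
        lab <- sample(ecOther, 1)
        ann <- members[runif(length(members)) < 0.9]
        if (length(ann)) ecTable[ann] <- lab
      }
    }
    new("PangenomeFixture", proteomes = proteomes, phenotype = pheno,
        ecTable = ecTable, groupTruth = groupTruth,
        causalGroup = causalMembers, seed = as.integer(seed))
  })
}

#' Orthogroups from recorded fixture truth
#'
#' Builds an [OrthogroupSet-class] directly from a pangenome fixture's
#' recorded group membership, bypassing sequence clustering. Used to study
#' the screen's statistical behaviour (presence patterns vs phenotype) in
#' isolation from clustering; [clusterOrthogroups()] recovers the same
#' partition from the sequences alone.
#'
#' @param fixture a [PangenomeFixture-class].
#' @return an [OrthogroupSet-class].
#' @export
trueOrthogroups <- function(fixture) {
  stopifnot(is(fixture, "PangenomeFixture"))
  truth <- groupTruth(fixture)
  strainOf <- rep(names(proteomes(fixture)),
                  lengths(proteomes(fixture)))
  names(strainOf) <- unlist(lapply(proteomes(fixture), names),
                            use.names = FALSE)
  makeOrthogroupSet(data.frame(protein = names(truth),
                               strain = unname(strainOf[names(truth)]),
                               group = unname(truth),
                               stringsAsFactors = FALSE),
                    strains = names(proteomes(fixture)))
}

#' Simulate a BilR protein family with classification ground truth
#'
#' Clade-1 members share a mutationally diverged common core carrying the
#' HGDR motif at reference positions `motifStart..motifStart+3`; long
#' members append a diverged NAD(P)H-binding extension and are annotated
#' with Pfam domains PF07992 + PF00724, short members with PF00724 alone.
#' Decoys each violate exactly one planted classification filter, cycling
#' through: "motif" (core-like but motif mutated to HGAA, the D->A / R->A
#' double mutant), "length" (core truncated below half the reference
#' length), "domain" (an extra PF01266 domain), "evalue" (an unrelated
#' random sequence). The clade-1 alignment (core columns, extension columns
#' gapped for short members) and the reference id for the first-373-residue
#' profile span are recorded.
#'
#' @param nShort,nLong,nDecoys member counts; `nShort + nLong >= 2`.
#' @param seed RNG seed.
#' @param coreLength,extLength residue lengths of the shared core and the
#'   long-form extension.
#' @param divergence per-residue substitution rate within the clade.
#' @param motifStart first motif residue position on the reference.
#' @param decoyTypes optional character vector recycled over the decoys;
#'   subset of motif, length, domain, evalue.
#' @return a [BilrFamilyFixture-class].
#' @examples
#' fam <- generateBilrFamily(3, 3, 4, seed = 1)
#' table(familyTruth(fam))
#' @export
generateBilrFamily <- function(nShort, nLong, nDecoys, seed,
                               coreLength = 380L, extLength = 160L,
                               divergence = 0.08, motifStart = 164L,
                               decoyTypes = NULL) {
  if (nShort + nLong + nDecoys < 1) stop("all counts are zero")
  if (nShort + nLong < 2) stop("need >= 2 clade-1 members to build a profile")
  if (motifStart + 3L > coreLength) stop("motif must lie within the core")
  withSeed(seed, {
    motifPos <- motifStart + 0:3
    core <- paste(sample(AA_STANDARD, coreLength, TRUE), collapse = "")
    core <- `substr<-`(core, motifStart, motifStart + 3L, "HGDR")
    ext <- paste(sample(AA_STANDARD, extLength, TRUE), collapse = "")
    gapExt <- strrep("-", extLength)

    ids <- character(0); seqs <- character(0); aln <- character(0)
    truth <- character(0); motifTruth <- character(0)
    domains <- list(); decoyType <- character(0)

    for (i in seq_len(nShort)) {
      id <- sprintf("short%02d", i)
      s <- mutateAA(core, divergence, protect = motifPos)
      ids <- c(ids, id); seqs <- c(seqs, s)
      aln[id] <- paste0(s, gapExt)
      truth[id] <- "clade1_short"; motifTruth[id] <- "HGDR"
      domains[[id]] <- "PF00724"
    }
    for (i in seq_len(nLong)) {
      id <- sprintf("long%02d", i)
      s <- mutateAA(core, divergence, protect = motifPos)
      e <- mutateAA(ext, divergence)
      ids <- c(ids, id); seqs <- c(seqs, paste0(s, e))
      aln[id] <- paste0(s, e)
      truth[id] <- "clade1_long"; motifTruth[id] <- "HGDR"
      domains[[id]] <- c("PF07992", "PF00724")
    }
    refId <- if (nLong >= 1) "long01" else "short01"
    refLen <- nchar(seqs[match(refId, ids)])

    kinds <- if (is.null(decoyTypes))
      rep_len(c("motif", "length", "domain", "evalue"), nDecoys)
    else rep_len(decoyTypes, nDecoys)
    for (i in seq_len(nDecoys)) {
      id <- sprintf("decoy%02d", i)
      kind <- kinds[i]
      if (kind == "motif") {
        s <- mutateAA(core, divergence, protect = motifPos)
        s <- `substr<-`(s, motifStart + 2L, motifStart + 3L, "AA")
        mt <- "HGAA"; dom <- "PF00724"
      } else if (kind == "length") {
        s <- mutateAA(core, divergence, protect = motifPos)
        s <- substr(s, 1L, floor(0.45 * refLen))
        mt <- "HGDR"; dom <- "PF00724"
      } else if (kind == "domain") {
        s <- mutateAA(core, divergence, protect = motifPos)
        mt <- "HGDR"; dom <- c("PF00724", "PF01266")
      } else if (kind == "evalue") {
        s <- paste(sample(AA_STANDARD, coreLength, TRUE), collapse = "")
        mt <- substr(s, motifStart, motifStart + 3L)
        dom <- "PF00724"
      } else stop("unknown decoy type: ", kind)
      ids <- c(ids, id); seqs <- c(seqs, s)
      truth[id] <- "decoy"; motifTruth[id] <- mt
      domains[[id]] <- dom; decoyType[id] <- kind
    }

    new("BilrFamilyFixture",
        sequences = Biostrings::AAStringSet(setNames(seqs, ids)),
        truth = truth, motifTruth = motifTruth, domainTable = domains,
        decoyType = decoyType,
        alignment = Biostrings::AAStringSet(aln),
        referenceId = refId, motifStart = as.integer(motifStart),
        seed = as.integer(seed))
  })
}

sampleSubstrings <- function(ref, n, readLength) {
  if (n == 0L) return(character(0))
  starts <- sample.int(nchar(ref) - readLength + 1L, n, replace = TRUE)
  out <- substring(ref, starts, starts + readLength - 1L)
  flip <- runif(n) < 0.5
  if (any(flip))
    out[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out[flip])))
  out
}

#' Simulate a shotgun metagenome collection with known bilR content
#'
#' Per-sample reads are drawn from three origins — the bilR gene reference
#' set, the host (contaminant) reference, and a random background genome —
#' with deterministic per-origin counts `round(fraction * readsPerSample)`
#' (read positions, strands and error positions remain random). Counts are
#' deterministic rather than multinomial so that a sample's true bilR CPM
#' is exactly `geneFraction * 1e6` and presence truth is recoverable even
#' when the expected gene-read count is a single read. Per-base
#' substitution errors are applied at `errorRate`; qualities are constant
#' Phred 40 (`"I"`), as no downstream stage consumes quality.
#'
#' @param nSamples,readsPerSample collection dimensions.
#' @param geneFractions numeric of length `nSamples`: fraction of each
#'   sample's reads drawn from the gene references.
#' @param hostFraction fraction of host-derived reads per sample.
#' @param errorRate per-base substitution error rate.
#' @param seed RNG seed.
#' @param readLength read length (uniform per fixture).
#' @param nGeneRefs,geneLength,hostLength,bgLength reference dimensions.
#' @param cohorts,ageDays optional per-sample metadata (recycled); cohort
#'   labels from infant, healthy_adult, ibd_cd, ibd_uc, other.
#' @return a [MetagenomeFixture-class].
#' @examples
#' mg <- generateMetagenome(2, 500, c(0, 0.01), hostFraction = 0.2,
#'                          errorRate = 0, seed = 1)
#' truthPresence(mg)
#' @export
generateMetagenome <- function(nSamples, readsPerSample, geneFractions,
                               hostFraction = 0.2, errorRate = 0.01, seed,
                               readLength = 100L, nGeneRefs = 3L,
                               geneLength = 1100L, hostLength = 20000L,
                               bgLength = 200000L, cohorts = NULL,
                               ageDays = NULL) {
  if (length(geneFractions) != nSamples)
    stop("'geneFractions' must have one entry per sample")
  if (any(geneFractions < 0 | geneFractions > 1) ||
      hostFraction < 0 || hostFraction > 1)
    stop("fractions must lie in [0, 1]")
  if (any(geneFractions + hostFraction > 1))
    stop("geneFraction + hostFraction must be <= 1 for every sample")
  if (errorRate < 0 || errorRate >= 1) stop("'errorRate' must be in [0, 1)")
  withSeed(seed, {
    sampleIds <- sprintf("S%03d", seq_len(nSamples))
    refs <- Biostrings::DNAStringSet(setNames(
      vapply(seq_len(nGeneRefs), function(i) randomDNA(geneLength),
             character(1)),
      sprintf("bilR_ref%d", seq_len(nGeneRefs))))
    host <- Biostrings::DNAStringSet(setNames(randomDNA(hostLength),
                                              "host_chr"))
    bg <- randomDNA(bgLength)
    refChars <- as.character(refs)

    reads <- vector("list", nSamples)
    names(reads) <- sampleIds
    for (i in seq_len(nSamples)) {
      nGene <- as.integer(round(geneFractions[i] * readsPerSample))
      nHost <- as.integer(round(hostFraction * readsPerSample))
      nBg <- readsPerSample - nGene - nHost
      geneSrc <- if (nGene > 0) sample.int(nGeneRefs, nGene, TRUE) else
        integer(0)
      gr <- vapply(geneSrc, function(r)
        sampleSubstrings(refChars[r], 1L, readLength), character(1))
      hr <- sampleSubstrings(as.character(host[[1]]), nHost, readLength)
      br <- sampleSubstrings(bg, nBg, readLength)
      sq <- c(gr, hr, br)
      origin <- rep(c("gene", "host", "bg"), c(nGene, nHost, nBg))
      sq <- mutate_reads_core(sq, errorRate)
      ord <- sample.int(length(sq))
      sq <- sq[ord]; origin <- origin[ord]
      names(sq) <- sprintf("%s_r%06d_%s", sampleIds[i],
                           seq_along(sq), origin)
      reads[[i]] <- Biostrings::DNAStringSet(sq)
    }
    meta <- data.frame(
      sample = sampleIds,
      cohort = if (is.null(cohorts)) "other" else rep_len(cohorts, nSamples),
      ageDays = if (is.null(ageDays)) NA_integer_ else
        as.integer(rep_len(ageDays, nSamples)),
      stringsAsFactors = FALSE)
    new("MetagenomeFixture", reads = reads, meta = meta, geneRefs = refs,
        hostRef = host,
        truthPresence = setNames(geneFractions > 0, sampleIds),
        truthGeneFraction = setNames(geneFractions, sampleIds),
        readLength = as.integer(readLength), errorRate = errorRate,
        seed = as.integer(seed))
  })
}

#' Per-read origin truth of a metagenome fixture
#'
#' Read ids carry their origin (`gene`, `host` or `bg`) as a suffix; this
#' recovers it as a factor aligned with [sampleReads()].
#'
#' @param fixture a [MetagenomeFixture-class].
#' @param sample sample id.
#' @return factor of origins, one per read.
#' @export
readOrigins <- function(fixture, sample) {
  ids <- names(sampleReads(fixture, sample))
  factor(sub(".*_", "", ids), levels = c("gene", "host", "bg"))
}

#' Simulate a fluorescence assay plate
#'
#' Planted reducer strains have mean fluorescence `foldChange` times the
#' abiotic-control mean; non-reducers match the control mean. Replicate
#' noise is lognormal with coefficient of variation `cv` (the lognormal is
#' parameterized so group means are exact in expectation).
#'
#' @param strains character vector of strain ids.
#' @param foldChange positive mean ratio of reducers to control.
#' @param cv replicate coefficient of variation (>= 0).
#' @param nReps replicates per strain (>= 3).
#' @param seed RNG seed.
#' @param reducers strain ids planted as reducers; default the first half.
#' @param controlMean,nControl abiotic control mean and replicate count.
#' @return a [FluorescenceFixture-class].
#' @examples
#' fl <- generateFluorescence(c("a", "b", "c", "d"), foldChange = 20,
#'                            cv = 0.05, nReps = 3, seed = 1)
#' truthReducer(fl)
#' @export
generateFluorescence <- function(strains, foldChange = 20, cv = 0.1,
                                 nReps = 3L, seed, reducers = NULL,
                                 controlMean = 1000, nControl = nReps) {
  if (foldChange <= 0) stop("'foldChange' must be > 0")
  if (nReps < 3) stop("'nReps' must be >= 3")
  if (cv < 0) stop("'cv' must be >= 0")
  if (is.null(reducers))
    reducers <- strains[seq_len(ceiling(length(strains) / 2))]
  if (!all(reducers %in% strains)) stop("'reducers' must be a subset of strains")
  withSeed(seed, {
    sigma <- sqrt(log(1 + cv^2))
    draw <- function(m, n) rlnorm(n, meanlog = log(m) - sigma^2 / 2,
                                  sdlog = sigma)
    meas <- lapply(setNames(strains, strains), function(s)
      draw(if (s %in% reducers) foldChange * controlMean else controlMean,
           nReps))
    ctrl <- draw(controlMean, nControl)
    new("FluorescenceFixture", measurements = meas, control = ctrl,
        truthReducer = setNames(strains %in% reducers, strains),
        seed = as.integer(seed))
  })
}
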