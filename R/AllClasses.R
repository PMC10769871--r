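#' @include bilRscreen-package.R
#' @importClassesFrom Biostrings AAStringSet DNAStringSet XStringSet
NULL

#' Pipeline configuration
#'
#' Single source of truth for every numeric threshold used by the pipeline:
#' the fluorescence reducer ratio (5, strict), the HMM-hit E-value ceiling
#' (1e-100, strict), the 50% length fraction, the HGDR motif, the CPM
#' presence threshold (5, strict), the one-million-read sample QC floor,
#' 30-day infant age bins over the first year, and the 3-year minimum age
#' for healthy-adult cohorts, plus mapper/HMM/clustering parameters. Stage
#' functions default their threshold arguments from a config object so no
#' threshold is duplicated in stage code.
#'
#' @slot fluorescenceThreshold ratio of sample to abiotic-control mean
#'   fluorescence above which (strictly) a strain is called a reducer.
#' @slot evalueMax HMM hits with E-value strictly below this are kept.
#' @slot minLengthFraction minimum target length as a fraction of the
#'   profile's reference protein length.
#' @slot motif residues required at the conserved motif columns.
#' @slot cpmThreshold a sample is bilR-positive when CPM strictly exceeds this.
#' @slot minReads samples with fewer reads fail QC (boundary inclusive).
#' @slot ageBinWidthDays,ageRangeDays infant age binning (half-open bins).
#' @slot healthyMinAgeYears healthy-cohort minimum age.
#' @slot hostK,hostMinSharedFraction host-read subtraction k-mer size and
#'   shared-fraction removal threshold.
#' @slot mapK,mapMinIdentity read-mapper seed size and ungapped identity floor.
#' @slot gapOpen,gapExtend,minScoreRatio protein alignment and
#'   reciprocal-best-hit clustering parameters (BLOSUM62 scoring).
#' @slot ecMinMembers minimum number of class-1 ("EC 1.-.-.-") annotated
#'   members for an orthogroup to pass the oxidoreductase filter.
#' @slot ecAllMembers alternative reading of the oxidoreductase filter: all
#'   members must be class-1 annotated and the group must exceed 2 members.
#' @slot cpmDenominator "filtered" (post host removal, default) or "raw".
#' @slot calibrationN,calibrationLength number and length of background
#'   sequences used for Gumbel E-value calibration.
#' @slot seed default RNG seed for stages with stochastic steps.
#' @export
setClass("BilrConfig", representation(
  fluorescenceThreshold = "numeric",
  evalueMax = "numeric",
  minLengthFraction = "numeric",
  motif = "character",
  cpmThreshold = "numeric",
  minReads = "numeric",
  ageBinWidthDays = "numeric",
  ageRangeDays = "numeric",
  healthyMinAgeYears = "numeric",
  hostK = "integer",
  hostMinSharedFraction = "numeric",
  mapK = "integer",
  mapMinIdentity = "numeric",
  gapOpen = "numeric",
  gapExtend = "numeric",
  minScoreRatio = "numeric",
  ecMinMembers = "integer",
  ecAllMembers = "logical",
  cpmDenominator = "character",
  calibrationN = "integer",
  calibrationLength = "integer",
  seed = "integer"))

setValidity("BilrConfig", function(object) {
  num <- c("fluorescenceThreshold", "evalueMax", "minLengthFraction",
           "cpmThreshold", "minReads", "ageBinWidthDays", "ageRangeDays",
           "healthyMinAgeYears", "hostK", "hostMinSharedFraction", "mapK",
           "mapMinIdentity", "gapOpen", "gapExtend", "minScoreRatio",
           "ecMinMembers", "calibrationN", "calibrationLength")
  for (s in num) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v <= 0)
      return(sprintf("slot '%s' must be a single positive number", s))
  }
  if (!nzchar(object@motif)) return("'motif' must be a non-empty string")
  if (!object@cpmDenominator %in% c("filtered", "raw"))
    return("'cpmDenominator' must be \"filtered\" or \"raw\"")
  if (object@minLengthFraction > 1) return("'minLengthFraction' must be <= 1")
  TRUE
})

#' Synthetic pangenome with a planted causal orthogroup
#'
#' Emulates the comparative-genomics input: per-strain proteomes for a set
#' of confirmed bilirubin reducers and closely related non-reducers, an EC
#' annotation table, and (optionally) one planted orthogroup whose strain
#' presence exactly tracks the reducer phenotype. Ground truth (full group
#' membership and the planted causal members) is recorded.
#'
#' @slot proteomes named list of [Biostrings::AAStringSet], one per strain.
#' @slot phenotype named character, per strain: "reducer" or "non_reducer".
#' @slot ecTable named character mapping protein ids to EC number strings;
#'   unannotated proteins are absent from the table.
#' @slot groupTruth named character mapping every protein id to its true
#'   orthogroup id.
#' @slot causalGroup character vector of planted causal protein ids (empty
#'   when no causal group was planted).
#' @slot seed integer seed the fixture was generated with.
#' @export
setClass("PangenomeFixture", representation(
  proteomes = "list", phenotype = "character", ecTable = "character",
  groupTruth = "character", causalGroup = "character", seed = "integer"))

setValidity("PangenomeFixture", function(object) {
  ids <- unlist(lapply(object@proteomes, names), use.names = FALSE)
  if (anyDuplicated(ids)) return("protein ids are not unique across strains")
  if (any(lengths(object@proteomes) == 0L))
    return("every strain must contribute at least one protein")
  if (!setequal(names(object@proteomes), names(object@phenotype)))
    return("phenotype must be given for exactly the strains present")
  if (!all(object@phenotype %in% c("reducer", "non_reducer")))
    return("phenotype labels must be 'reducer' or 'non_reducer'")
  if (length(object@causalGroup)) {
    red <- names(object@phenotype)[object@phenotype == "reducer"]
    non <- names(object@phenotype)[object@phenotype == "non_reducer"]
    strainOf <- rep(names(object@proteomes), lengths(object@proteomes))
    names(strainOf) <- ids
    cs <- unique(strainOf[object@causalGroup])
    if (!setequal(cs, red))
      return("causal group must be present in every reducer and no other strain")
    if (any(cs %in% non)) return("causal group leaked into a non-reducer")
  }
  TRUE
})

#' Synthetic BilR protein family with classification truth
#'
#' Emulates the family the profile-HMM stage scans: clade-1 bilirubin
#' reductases (short, TIM-barrel only; long, with an additional
#' NAD(P)H-binding region) sharing a conserved core with the HGDR motif,
#' plus decoys that each violate one classification filter (motif, length,
#' domain architecture or homology/E-value). Carries the clade-1 multiple
#' alignment used to build the profile, a Pfam-style domain table, and
#' per-protein truth labels.
#'
#' @slot sequences [Biostrings::AAStringSet] of all family members.
#' @slot truth named character: "clade1_short", "clade1_long" or "decoy".
#' @slot motifTruth named character: 4-residue string at the motif columns.
#' @slot domainTable named list of character vectors of Pfam accessions.
#' @slot decoyType named character (decoys only): the violated filter, one
#'   of "motif", "length", "domain", "evalue".
#' @slot alignment aligned [Biostrings::AAStringSet] of the clade-1 members.
#' @slot referenceId id of the alignment row whose first 373 residues span
#'   the TIM-barrel region modelled by the profile.
#' @slot motifStart first of the four consecutive motif residue positions on
#'   the reference protein.
#' @slot seed integer generation seed.
#' @export
setClass("BilrFamilyFixture", representation(
  sequences = "AAStringSet", truth = "character", motifTruth = "character",
  domainTable = "list", decoyType = "character", alignment = "AAStringSet",
  referenceId = "character", motifStart = "integer", seed = "integer"))

setValidity("BilrFamilyFixture", function(object) {
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids)) return("sequence ids must be unique")
  if (!setequal(ids, names(object@truth))) return("truth must cover all ids")
  cl1 <- names(object@truth)[object@truth != "decoy"]
  if (!all(object@motifTruth[cl1] == "HGDR"))
    return("clade-1 members must carry HGDR in motifTruth")
  if (!all(names(object@decoyType) %in%
           names(object@truth)[object@truth == "decoy"]))
    return("decoyType keys must be decoys")
  TRUE
})

#' Synthetic shotgun metagenome collection with known bilR content
#'
#' Per-sample read sets drawn from a bilR gene reference set, a host
#' (contaminant) reference and random background in recorded proportions,
#' with uniform read length, per-base substitution errors and constant
#' Phred-40 qualities. Read ids encode their origin
#' (\code{<sample>_r<idx>_<gene|host|bg>}) so mapping results can be checked
#' against truth exactly.
#'
#' @slot reads named list of [Biostrings::DNAStringSet], one per sample.
#' @slot meta data.frame with columns sample, cohort, ageDays (NA allowed).
#' @slot geneRefs [Biostrings::DNAStringSet] bilR gene reference sequences.
#' @slot hostRef [Biostrings::DNAStringSet] host reference sequence(s).
#' @slot truthPresence named logical: whether any reads of the sample were
#'   drawn from the gene references.
#' @slot truthGeneFraction named numeric: fraction of reads drawn from the
#'   gene references.
#' @slot readLength,errorRate,seed generation parameters.
#' @export
setClass("MetagenomeFixture", representation(
  reads = "list", meta = "data.frame", geneRefs = "DNAStringSet",
  hostRef = "DNAStringSet", truthPresence = "logical",
  truthGeneFraction = "numeric", readLength = "integer",
  errorRate = "numeric", seed = "integer"))

setValidity("MetagenomeFixture", function(object) {
  ids <- names(object@reads)
  if (!identical(sort(ids), sort(object@meta$sample)))
    return("meta must describe exactly the samples present")
  if (!identical(object@truthPresence[ids],
                 setNames(object@truthGeneFraction[ids] > 0, ids)))
    return("truthPresence must equal truthGeneFraction > 0")
  for (s in ids) {
    w <- Biostrings::width(object@reads[[s]])
    if (length(w) && !all(w == object@readLength))
      return("read lengths must be uniform")
  }
  TRUE
})

#' Synthetic fluorescence assay plate with known reducer truth
#'
#' Replicate urobilin-fluorescence measurements per strain plus abiotic
#' media control replicates. Planted reducers have mean fluorescence equal
#' to \code{foldChange} times the control mean; noise is lognormal with a
#' stated coefficient of variation.
#'
#' @slot measurements named list of numeric replicate vectors per strain.
#' @slot control numeric abiotic-control replicate values (all positive).
#' @slot truthReducer named logical planted phenotype.
#' @slot seed integer generation seed.
#' @export
setClass("FluorescenceFixture", representation(
  measurements = "list", control = "numeric", truthReducer = "logical",
  seed = "integer"))

setValidity("FluorescenceFixture", function(object) {
  if (any(lengths(object@measurements) < 3L))
    return("at least 3 replicates per strain are required")
  if (!length(object@control) || any(object@control <= 0))
    return("control values must be strictly positive")
  if (!setequal(names(object@measurements), names(object@truthReducer)))
    return("truthReducer must cover exactly the measured strains")
  TRUE
})

#' A set of orthogroups over a multi-strain protein universe
#'
#' The unit of the comparative screen: a partition of all proteins into
#' groups (singletons allowed), each with a strain presence vector.
#'
#' @slot membership data.frame with columns protein, strain, group.
#' @slot presence logical matrix, groups x strains; TRUE iff the group has
#'   at least one member from that strain.
#' @export
setClass("OrthogroupSet", representation(
  membership = "data.frame", presence = "matrix"))

setValidity("OrthogroupSet", function(object) {
  m <- object@membership
  if (!all(c("protein", "strain", "group") %in% colnames(m)))
    return("membership needs columns protein, strain, group")
  if (anyDuplicated(m$protein))
    return("orthogroups must partition the proteins (duplicate member)")
  if (!setequal(rownames(object@presence), unique(m$group)))
    return("presence rows must match the groups")
  tab <- table(m$group, m$strain) > 0
  pr <- object@presence[rownames(tab), colnames(tab), drop = FALSE]
  if (!identical(unname(pr), unname(as.matrix(tab) == TRUE)) &&
      !all(pr == (as.matrix(tab) > 0)))
    return("presence must be TRUE iff >= 1 member from that strain")
  TRUE
})

#' Profile hidden Markov model of a protein domain
#'
#' A Plan-7-style profile over selected alignment match columns: per-column
#' match emission distributions, a background insert emission distribution,
#' match/insert/delete transition probabilities, the indices of the four
#' consecutive match columns homologous to the conserved HGDR motif, the
#' reference protein length used by the 50%-length filter, and (after
#' [calibrate()]) Gumbel E-value parameters.
#'
#' @slot matchEmissions numeric matrix, match columns x 20 residues; rows
#'   sum to 1.
#' @slot insertEmissions numeric length-20 insert/background emission
#'   distribution.
#' @slot transitions named list of per-column transition probability
#'   vectors: MM, MI, MD, II, IM, DD, DM (source-column indexed).
#' @slot background numeric length-20 null-model residue distribution.
#' @slot motifColumns integer(4), consecutive match-column indices of the
#'   motif.
#' @slot referenceLength integer residue length of the reference protein.
#' @slot mu,lambda Gumbel location and scale of the null score
#'   distribution; NA until calibrated.
#' @export
setClass("ProfileHMM", representation(
  matchEmissions = "matrix", insertEmissions = "numeric",
  transitions = "list", background = "numeric", motifColumns = "integer",
  referenceLength = "integer", mu = "numeric", lambda = "numeric"))

setValidity("ProfileHMM", function(object) {
  L <- nrow(object@matchEmissions)
  if (ncol(object@matchEmissions) != 20L)
    return("matchEmissions must have 20 residue columns")
  if (any(abs(rowSums(object@matchEmissions) - 1) > 1e-9))
    return("match emission rows must sum to 1")
  if (abs(sum(object@insertEmissions) - 1) > 1e-9 ||
      abs(sum(object@background) - 1) > 1e-9)
    return("insert and background emissions must sum to 1")
  tr <- object@transitions
  if (!all(c("MM", "MI", "MD", "II", "IM", "DD", "DM") %in% names(tr)))
    return("transitions must contain MM, MI, MD, II, IM, DD, DM")
  outM <- tr$MM + tr$MI + tr$MD
  outI <- tr$II + tr$IM
  outD <- tr$DD + tr$DM
  if (any(abs(c(outM, outI, outD) - 1) > 1e-9))
    return("outgoing transition distributions must sum to 1")
  if (length(object@motifColumns)) {
    mc <- object@motifColumns
    if (length(mc) != 4L || any(mc < 1L | mc > L) ||
        !all(diff(mc) == 1L))
      return("motifColumns must be 4 consecutive valid match columns")
  }
  if (!is.na(object@lambda) && object@lambda <= 0)
    return("calibrated lambda must be > 0")
  TRUE
})

#' A profile-HMM search hit
#'
#' Result of a local Viterbi search of one target sequence: the bit score,
#' the aligned region (1-based inclusive on the target), a map from every
#' profile match column to the target residue position aligned to it (0 =
#' column outside the aligned region, -1 = deletion), and, once the profile
#' is calibrated and a database size given, an E-value.
#'
#' @slot targetId character target identifier.
#' @slot score numeric Viterbi log-odds score in bits.
#' @slot evalue numeric E-value (NA until assigned).
#' @slot region integer(2) aligned start/end on the target (0,0 when the
#'   best local alignment is empty).
#' @slot matchMap integer vector over match columns (see above).
#' @export
setClass("HmmHit", representation(
  targetId = "character", score = "numeric", evalue = "numeric",
  region = "integer", matchMap = "integer"))

setValidity("HmmHit", function(object) {
  if (length(object@region) != 2L) return("region must be integer(2)")
  if (!is.na(object@evalue) && object@evalue < 0)
    return("E-value must be >= 0")
  TRUE
})

#' A BilR classification call with its filter audit
#'
#' Outcome of the four-part quality-control filter applied to a profile-HMM
#' hit: E-value strictly below the ceiling, target at least the required
#' fraction of the reference length, the HGDR motif read off the motif
#' match columns with no gaps, and exactly the expected Pfam domain set
#' (PF00724 alone for short BilR; PF07992 + PF00724 for long BilR). The
#' verdict is "none" unless all four filters pass.
#'
#' @slot targetId character.
#' @slot verdict "none", "short" or "long".
#' @slot evaluePass,lengthPass,motifPass,domainPass logical filter audit.
#' @slot motifObserved 4-character string read off the motif columns ("-"
#'   for gap/uncovered).
#' @slot domainReason character: "ok", "unannotated" or "unexpected_set".
#' @slot evalue,score numeric supporting values.
#' @export
setClass("BilRCall", representation(
  targetId = "character", verdict = "character", evaluePass = "logical",
  lengthPass = "logical", motifPass = "logical", domainPass = "logical",
  motifObserved = "character", domainReason = "character",
  evalue = "numeric", score = "numeric"))

setValidity("BilRCall", function(object) {
  if (!object@verdict %in% c("none", "short", "long"))
    return("verdict must be none, short or long")
  allPass <- object@evaluePass && object@lengthPass && object@motifPass &&
    object@domainPass
  if ((object@verdict != "none") != allPass)
    return("verdict must be non-none iff all four filters pass")
  TRUE
})

#' Result of the phenotype-guided candidate screen
#'
#' @slot candidates character vector of candidate orthogroup ids.
#' @slot audit data.frame per group: class-1 EC member count, oxidoreductase
#'   filter outcome, Hamming distance of the presence vector to the
#'   phenotype vector, pattern-match outcome, candidate flag.
#' @slot phenotype named character phenotype table used.
#' @slot mode "strict" or "scored".
#' @export
setClass("ScreenResult", representation(
  candidates = "character", audit = "data.frame", phenotype = "character",
  mode = "character"))

setValidity("ScreenResult", function(object) {
  a <- object@audit
  if (nrow(a) && !all(object@candidates %in% a$group[a$candidate]))
    return("candidates must be flagged in the audit")
  TRUE
})

#' Two-group prevalence comparison (test of equal proportions)
#'
#' @slot groups character(2) group labels.
#' @slot n,absent integer(2) samples and bilR-absent samples per group.
#' @slot proportionDiff numeric difference of absence proportions (1 - 2).
#' @slot statistic,pValue chi-square statistic (1 df) and p-value.
#' @slot correct logical whether the Yates continuity correction was used.
#' @export
setClass("PrevalenceResult", representation(
  groups = "character", n = "integer", absent = "integer",
  proportionDiff = "numeric", statistic = "numeric", pValue = "numeric",
  correct = "logical"))

setValidity("PrevalenceResult", function(object) {
  if (any(object@absent > object@n)) return("absent cannot exceed n")
  if (object@statistic < 0) return("statistic must be >= 0")
  p <- object@absent / object@n
  if (abs(object@proportionDiff - (p[1] - p[2])) > 1e-12)
    return("proportionDiff inconsistent with counts")
  TRUE
})
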