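#' @include config.R
NULL

COHORT_LEVELS <- c("infant", "healthy_adult", "ibd_cd", "ibd_uc", "other")

#' Remove host-derived reads by shared k-mers
#'
#' A read is flagged as host contamination and removed when the fraction
#' of its k-mers (canonical, strand-collapsed) found in the host reference
#' reaches `minSharedFraction`. The retained reads keep their input order.
#'
#' @param reads a [Biostrings::DNAStringSet].
#' @param hostReference a [Biostrings::DNAStringSet] (or character) host
#'   reference; must be non-empty.
#' @param config a [BilrConfig-class].
#' @param k k-mer size (<= 32 and <= read length).
#' @param minSharedFraction removal threshold on the shared fraction.
#' @return the retained [Biostrings::DNAStringSet].
#' @export
subtractHost <- function(reads, hostReference, config = bilrConfig(),
                         k = config@hostK,
                         minSharedFraction = config@hostMinSharedFraction) {
  host <- as.character(hostReference)
  if (!length(host) || !any(nzchar(host)))
    stop("host reference must be non-empty")
  if (!length(reads)) return(reads)
  if (k > min(Biostrings::width(reads)))
    stop("'k' exceeds the read length")
  flag <- shared_kmer_fraction(as.character(reads), host, as.integer(k),
                               decideAt = minSharedFraction)
  reads[flag < 1]
}

#' Sample read-depth quality control
#'
#' A sample passes QC iff it has at least `minReads` reads (the boundary
#' is inclusive: exactly the minimum passes). Samples failing QC are
#' excluded from presence calling.
#'
#' @param reads a [Biostrings::DNAStringSet] or a read count.
#' @param config a [BilrConfig-class].
#' @param minReads read floor (default one million).
#' @return logical.
#' @export
qcSample <- function(reads, config = bilrConfig(),
                     minReads = config@minReads) {
  n <- if (is.numeric(reads)) reads else length(reads)
  n >= minReads
}

#' Count reads mapping to the bilR gene reference set
#'
#' Seed-and-extend presence mapping: a read counts as mapped iff it shares
#' at least one exact k-mer with any reference (either strand) and an
#' ungapped extension along the seed diagonal reaches `minIdentity` over
#' the whole read. Each read is counted at most once however many
#' references it hits.
#'
#' @param reads a [Biostrings::DNAStringSet].
#' @param geneReferences a non-empty [Biostrings::DNAStringSet].
#' @param config a [BilrConfig-class].
#' @param k seed k-mer size (<= 32 and <= read length).
#' @param minIdentity ungapped identity floor over the read.
#' @param what "count" (default) or "logical" (per-read mapped flag).
#' @return integer count, or logical vector when `what = "logical"`.
#' @export
mapReads <- function(reads, geneReferences, config = bilrConfig(),
                     k = config@mapK, minIdentity = config@mapMinIdentity,
                     what = c("count", "logical")) {
  what <- match.arg(what)
  refs <- as.character(geneReferences)
  if (!length(refs) || !any(nzchar(refs)))
    stop("gene reference set must be non-empty")
  if (!length(reads))
    return(if (what == "count") 0L else logical(0))
  if (k > min(Biostrings::width(reads)))
    stop("'k' exceeds the read length")
  hit <- map_reads_core(as.character(reads), refs, as.integer(k),
                        minIdentity)
  if (what == "count") sum(hit) else hit
}

#' bilR counts per million
#'
#' `mapped / total * 1e6`.
#'
#' @param mapped bilR-mapped read count (`<= total`).
#' @param total total sample reads (> 0).
#' @return numeric CPM.
#' @examples
#' computeCpm(123, 2345678)
#' @export
computeCpm <- function(mapped, total) {
  if (any(total <= 0)) stop("'total' must be > 0")
  if (any(mapped > total)) stop("'mapped' cannot exceed 'total'")
  if (any(mapped < 0)) stop("'mapped' must be >= 0")
  mapped / total * 1e6
}

#' Call bilR presence from CPM
#'
#' Present iff CPM strictly exceeds the threshold (default 5); exactly 5
#' CPM is absent.
#'
#' @param cpm non-negative CPM value(s).
#' @param config a [BilrConfig-class].
#' @param threshold CPM threshold.
#' @return logical.
#' @examples
#' callPresence(c(5, 5.01))
#' @export
callPresence <- function(cpm, config = bilrConfig(),
                         threshold = config@cpmThreshold) {
  if (any(cpm < 0)) stop("'cpm' must be >= 0")
  cpm > threshold
}

#' Per-sample bilR profiles for a metagenome collection
#'
#' The full per-sample workflow: host-read subtraction, read-depth QC,
#' mapping to the bilR reference set, CPM and the strict presence call.
#' The CPM denominator is the post-host-removal read count by default
#' (`config@cpmDenominator = "raw"` uses the raw count instead). Presence
#' is only defined (non-NA) for QC-passing samples.
#'
#' @param x a [MetagenomeFixture-class], or a named list of
#'   [Biostrings::DNAStringSet] read sets (then `geneReferences`,
#'   `hostReference` and `meta` must be given).
#' @param config a [BilrConfig-class]; note `minReads` should be scaled to
#'   the fixture's depth.
#' @param geneReferences,hostReference,meta inputs when `x` is a plain
#'   list of read sets.
#' @return data.frame with one row per sample: sample, cohort, ageDays,
#'   rawReads, totalReads (post host removal), mappedReads, cpm, qcPass,
#'   present.
#' @export
profileSamples <- function(x, config = bilrConfig(), geneReferences = NULL,
                           hostReference = NULL, meta = NULL) {
  if (is(x, "MetagenomeFixture")) {
    readSets <- sampleReads(x)
    geneReferences <- geneRefs(x)
    hostReference <- hostRef(x)
    meta <- sampleMeta(x)
  } else {
    readSets <- x
    if (is.null(geneReferences) || is.null(hostReference))
      stop("gene and host references are required")
    if (is.null(meta))
      meta <- data.frame(sample = names(readSets), cohort = "other",
                         ageDays = NA_integer_, stringsAsFactors = FALSE)
  }
  rows <- lapply(names(readSets), function(s) {
    rd <- readSets[[s]]
    kept <- subtractHost(rd, hostReference, config)
    total <- if (config@cpmDenominator == "raw") length(rd) else length(kept)
    mapped <- mapReads(kept, geneReferences, config)
    qc <- qcSample(kept, config)
    cpm <- if (total > 0) computeCpm(mapped, total) else NA_real_
    data.frame(sample = s, rawReads = length(rd), totalReads = length(kept),
               mappedReads = mapped, cpm = cpm, qcPass = qc,
               present = if (qc) callPresence(cpm, config) else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  merge(meta, out, by = "sample", sort = TRUE)
}

#' Bin infant samples by age and tabulate bilR absence
#'
#' Samples are assigned to half-open `[w * i, w * (i + 1))` age bins of
#' width `binWidthDays` across the first `rangeDays` days. Samples
#' without age metadata, beyond the range, or failing QC are excluded.
#'
#' @param profiles data.frame from [profileSamples()] (needs ageDays,
#'   qcPass, present).
#' @param config a [BilrConfig-class].
#' @param binWidthDays,rangeDays binning parameters.
#' @return data.frame per occupied bin: bin index, ageStartDays,
#'   nSamples, nAbsent, percentAbsent.
#' @export
binByAge <- function(profiles, config = bilrConfig(),
                     binWidthDays = config@ageBinWidthDays,
                     rangeDays = config@ageRangeDays) {
  age <- profiles$ageDays
  if (any(age < 0, na.rm = TRUE)) stop("negative age")
  keep <- !is.na(age) & age <= rangeDays & profiles$qcPass
  pf <- profiles[keep, , drop = FALSE]
  if (!nrow(pf))
    return(data.frame(bin = integer(0), ageStartDays = numeric(0),
                      nSamples = integer(0), nAbsent = integer(0),
                      percentAbsent = numeric(0)))
  bin <- floor(pf$ageDays / binWidthDays)
  tab <- lapply(sort(unique(bin)), function(b) {
    inBin <- bin == b
    n <- sum(inBin)
    ab <- sum(!pf$present[inBin])
    data.frame(bin = b, ageStartDays = b * binWidthDays, nSamples = n,
               nAbsent = ab, percentAbsent = 100 * ab / n)
  })
  do.call(rbind, tab)
}

#' Two-group test of equal proportions
#'
#' Compares the proportion of bilR-absent samples between two groups with
#' the chi-square test of equal proportions ([stats::prop.test()]
#' semantics; 1 df), with or without the Yates continuity correction.
#'
#' @param absent1,n1,absent2,n2 absent counts and group sizes
#'   (`0 <= absent_i <= n_i`, `n_i >= 1`).
#' @param correct apply the continuity correction (default TRUE, the
#'   `prop.test` default).
#' @param groups character(2) labels.
#' @return a [PrevalenceResult-class].
#' @examples
#' prevalenceTest(10, 100, 30, 100, correct = FALSE)
#' @export
prevalenceTest <- function(absent1, n1, absent2, n2, correct = TRUE,
                           groups = c("group1", "group2")) {
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1")
  if (absent1 < 0 || absent1 > n1 || absent2 < 0 || absent2 > n2)
    stop("absent counts must lie in [0, n]")
  ht <- suppressWarnings(
    prop.test(c(absent1, absent2), c(n1, n2), correct = correct))
  new("PrevalenceResult", groups = groups,
      n = as.integer(c(n1, n2)), absent = as.integer(c(absent1, absent2)),
      proportionDiff = absent1 / n1 - absent2 / n2,
      statistic = unname(ht$statistic), pValue = ht$p.value,
      correct = correct)
}

#' Apply cohort inclusion rules
#'
#' Healthy-adult samples below the minimum age (default 3 years) are
#' excluded; IBD samples are regrouped into "CD" and "UC"; infant samples
#' are retained (age binning applies its own exclusions); cohort labels
#' outside the known set are an error. Adds a `group` column; the counts
#' removed per cohort are attached as attribute `"audit"`.
#'
#' @param profiles data.frame from [profileSamples()].
#' @param config a [BilrConfig-class].
#' @return the retained rows with a `group` column.
#' @export
cohortFilter <- function(profiles, config = bilrConfig()) {
  bad <- setdiff(unique(profiles$cohort), COHORT_LEVELS)
  if (length(bad))
    stop("unknown cohort label(s): ", paste(bad, collapse = ", "))
  minDays <- config@healthyMinAgeYears * 365
  drop <- profiles$cohort == "healthy_adult" & !is.na(profiles$ageDays) &
    profiles$ageDays < minDays
  out <- profiles[!drop, , drop = FALSE]
  out$group <- c(infant = "infant", healthy_adult = "healthy",
                 ibd_cd = "CD", ibd_uc = "UC", other = "other")[out$cohort]
  audit <- table(factor(profiles$cohort[drop], levels = COHORT_LEVELS))
  attr(out, "audit") <- as.list(audit)
  rownames(out) <- NULL
  out
}

#' Compare bilR absence between two cohort groups
#'
#' Builds the 2x2 absence table over QC-passing samples of the two groups
#' and runs [prevalenceTest()].
#'
#' @param profiles data.frame with `group`, `qcPass`, `present` columns
#'   (see [cohortFilter()]).
#' @param groupA,groupB group labels to compare.
#' @param correct Yates continuity correction flag.
#' @return a [PrevalenceResult-class].
#' @export
comparePrevalence <- function(profiles, groupA, groupB, correct = TRUE) {
  pick <- function(g) {
    p <- profiles[profiles$group == g & profiles$qcPass, , drop = FALSE]
    if (!nrow(p)) stop("no QC-passing samples in group ", g)
    c(absent = sum(!p$present), n = nrow(p))
  }
  a <- pick(groupA); b <- pick(groupB)
  prevalenceTest(a["absent"], a["n"], b["absent"], b["n"],
                 correct = correct, groups = c(groupA, groupB))
}
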