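#' @include screen.R classify.R profiler.R
NULL

configAsList <- function(config) {
  vals <- lapply(slotNames(config), function(s) slot(config, s))
  names(vals) <- slotNames(config)
  vals
}

makeReport <- function(stage, counts, config, elapsed) {
  list(stages = counts, parameters = configAsList(config),
       seed = config@seed, workflow = stage,
       wallClockSeconds = as.numeric(elapsed))
}

#' Run the candidate-discovery workflow
#'
#' The comparative-genomics arm end to end: cluster the proteomes into
#' orthogroups by reciprocal best hits, screen them with the
#' oxidoreductase EC filter and the phenotype presence/absence pattern,
#' then build the clade profile from the family alignment, calibrate its
#' E-values, and classify every family protein as short/long BilR or
#' neither. Deterministic for a fixed config seed.
#'
#' @param pangenome a [PangenomeFixture-class] (or the value of
#'   [readPangenome()]).
#' @param family a [BilrFamilyFixture-class] (or [readBilrFamily()]), or
#'   NULL to skip the classification stage.
#' @param config a [BilrConfig-class].
#' @param clusterFromTruth use the fixture's recorded orthogroup
#'   membership instead of sequence clustering (isolates the screen's
#'   statistics from clustering; default FALSE).
#' @return list with elements `orthogroups` ([OrthogroupSet-class]),
#'   `screen` ([ScreenResult-class]), `profile` (calibrated
#'   [ProfileHMM-class] or NULL), `calls` (classification table or NULL)
#'   and `report`.
#' @export
runDiscovery <- function(pangenome, family = NULL, config = bilrConfig(),
                         clusterFromTruth = FALSE) {
  t0 <- Sys.time()
  og <- if (clusterFromTruth) trueOrthogroups(pangenome)
  else clusterOrthogroups(pangenome, config)
  screen <- screenCandidates(og, ecTable(pangenome), phenotype(pangenome),
                             config)
  profile <- NULL; calls <- NULL
  if (!is.null(family)) {
    profile <- calibrate(familyProfile(family),
                         nRandom = config@calibrationN,
                         randomLength = config@calibrationLength,
                         seed = config@seed)
    calls <- classifyDatabase(profile, sequences(family),
                              domainTable(family), config)
  }
  counts <- list(
    proteinsIn = sum(lengths(proteomes(pangenome))),
    orthogroups = length(groupIds(og)),
    oxidoreductaseGroups = sum(screenAudit(screen)$ecPass),
    candidates = length(candidates(screen)),
    familyProteins = if (is.null(family)) 0L else length(sequences(family)),
    bilrCalls = if (is.null(calls)) 0L else sum(calls$verdict != "none"))
  list(orthogroups = og, screen = screen, profile = profile, calls = calls,
       report = makeReport("discovery", counts, config,
                           difftime(Sys.time(), t0, units = "secs")))
}

#' Run the cohort-profiling workflow
#'
#' The metagenome arm end to end: per-sample host subtraction, QC,
#' mapping, CPM and presence calls; cohort inclusion rules; infant age
#' binning; and a test of equal proportions for every requested pair of
#' cohort groups (by default all pairs present in the data).
#'
#' @param metagenome a [MetagenomeFixture-class] (or [readMetagenome()]).
#' @param config a [BilrConfig-class]; set `minReads` to the fixture scale.
#' @param comparisons list of character(2) group-label pairs to compare,
#'   or NULL for all pairs with QC-passing samples.
#' @param correct Yates continuity correction for the proportion tests.
#' @return list with `profiles` (per-sample table), `ageBins`,
#'   `prevalence` (list of [PrevalenceResult-class]) and `report`.
#' @export
runProfiling <- function(metagenome, config = bilrConfig(),
                         comparisons = NULL, correct = TRUE) {
  t0 <- Sys.time()
  prof <- profileSamples(metagenome, config)
  prof <- cohortFilter(prof, config)
  bins <- binByAge(prof[prof$group == "infant", , drop = FALSE], config)
  groups <- unique(prof$group[prof$qcPass])
  if (is.null(comparisons) && length(groups) >= 2L)
    comparisons <- combn(sort(groups), 2L, simplify = FALSE)
  prevalence <- lapply(comparisons, function(pair)
    comparePrevalence(prof, pair[1], pair[2], correct = correct))
  names(prevalence) <- vapply(comparisons, paste, character(1),
                              collapse = "_vs_")
  counts <- list(
    samplesIn = nrow(sampleMeta(metagenome)),
    samplesRetained = nrow(prof),
    qcPass = sum(prof$qcPass),
    present = sum(prof$present, na.rm = TRUE),
    comparisons = length(prevalence))
  list(profiles = prof, ageBins = bins, prevalence = prevalence,
       report = makeReport("profiling", counts, config,
                           difftime(Sys.time(), t0, units = "secs")))
}

#' Write a machine-readable run report
#'
#' @param report the `report` element of [runDiscovery()] /
#'   [runProfiling()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
writeRunReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
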