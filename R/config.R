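#' @include AllClasses.R
NULL

#' Create a pipeline configuration
#'
#' All thresholds default to the study values: a fluorescence ratio of 5
#' (strictly above calls a reducer), an E-value ceiling of 1e-100 (strictly
#' below keeps a hit), a 50% reference-length floor, the HGDR motif, a CPM
#' presence threshold of 5 (strictly above), a one-million-read sample QC
#' floor (at least one million passes), 30-day age bins over the first 365
#' days, and a 3-year minimum age for healthy-adult cohorts.
#'
#' @param fluorescenceThreshold,evalueMax,minLengthFraction,motif,
#'   cpmThreshold,minReads,ageBinWidthDays,ageRangeDays,healthyMinAgeYears
#'   study thresholds; see [BilrConfig-class].
#' @param hostK,hostMinSharedFraction,mapK,mapMinIdentity read-processing
#'   parameters: host-subtraction k-mer size and removal fraction, mapper
#'   seed size and ungapped identity floor.
#' @param gapOpen,gapExtend,minScoreRatio BLOSUM62 affine-gap alignment and
#'   reciprocal-best-hit clustering parameters.
#' @param ecMinMembers,ecAllMembers oxidoreductase orthogroup filter: keep
#'   groups with at least `ecMinMembers` class-1 EC members ("more than 2"),
#'   or, under the alternative reading, groups larger than 2 whose members
#'   are all class-1.
#' @param cpmDenominator "filtered" (reads surviving host removal; default)
#'   or "raw" (all reads) as the CPM denominator.
#' @param calibrationN,calibrationLength Gumbel calibration sample.
#' @param seed default RNG seed.
#' @return a validated [BilrConfig-class] object.
#' @examples
#' cfg <- bilrConfig()
#' cfg@cpmThreshold
#' @export
bilrConfig <- function(fluorescenceThreshold = 5,
                       evalueMax = 1e-100,
                       minLengthFraction = 0.5,
                       motif = "HGDR",
                       cpmThreshold = 5,
                       minReads = 1e6,
                       ageBinWidthDays = 30,
                       ageRangeDays = 365,
                       healthyMinAgeYears = 3,
                       hostK = 31L,
                       hostMinSharedFraction = 0.5,
                       mapK = 21L,
                       mapMinIdentity = 0.9,
                       gapOpen = 11,
                       gapExtend = 1,
                       minScoreRatio = 0.3,
                       ecMinMembers = 3L,
                       ecAllMembers = FALSE,
                       cpmDenominator = c("filtered", "raw"),
                       calibrationN = 500L,
                       calibrationLength = 150L,
                       seed = 1L) {
  new("BilrConfig",
      fluorescenceThreshold = fluorescenceThreshold,
      evalueMax = evalueMax,
      minLengthFraction = minLengthFraction,
      motif = toupper(motif),
      cpmThreshold = cpmThreshold,
      minReads = minReads,
      ageBinWidthDays = ageBinWidthDays,
      ageRangeDays = ageRangeDays,
      healthyMinAgeYears = healthyMinAgeYears,
      hostK = as.integer(hostK),
      hostMinSharedFraction = hostMinSharedFraction,
      mapK = as.integer(mapK),
      mapMinIdentity = mapMinIdentity,
      gapOpen = gapOpen,
      gapExtend = gapExtend,
      minScoreRatio = minScoreRatio,
      ecMinMembers = as.integer(ecMinMembers),
      ecAllMembers = ecAllMembers,
      cpmDenominator = match.arg(cpmDenominator),
      calibrationN = as.integer(calibrationN),
      calibrationLength = as.integer(calibrationLength),
      seed = as.integer(seed))
}

#' Read / write a configuration as YAML
#'
#' The serialization round-trips: `readBilrConfig(writeBilrConfig(cfg, f))`
#' reconstructs an identical object. Unknown keys in the file are an error
#' (they would silently change nothing otherwise).
#'
#' @param config a [BilrConfig-class] object.
#' @param path file path.
#' @return `readBilrConfig` returns a [BilrConfig-class];
#'   `writeBilrConfig` returns `path` invisibly.
#' @export
writeBilrConfig <- function(config, path) {
  stopifnot(is(config, "BilrConfig"))
  vals <- lapply(setdiff(slotNames(config), character()), function(s)
    slot(config, s))
  names(vals) <- slotNames(config)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeBilrConfig
#' @export
readBilrConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(bilrConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(bilrConfig, vals)
}
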