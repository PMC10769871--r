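#' @include AllGenerics.R
NULL

#' @rdname bilRscreen-accessors
#' @export
setMethod("proteomes", "PangenomeFixture", function(x) x@proteomes)
#' @rdname bilRscreen-accessors
#' @export
setMethod("phenotype", "PangenomeFixture", function(x) x@phenotype)
#' @rdname bilRscreen-accessors
#' @export
setMethod("ecTable", "PangenomeFixture", function(x) x@ecTable)
#' @rdname bilRscreen-accessors
#' @export
setMethod("causalGroup", "PangenomeFixture", function(x) x@causalGroup)
#' @rdname bilRscreen-accessors
#' @export
setMethod("groupTruth", "PangenomeFixture", function(x) x@groupTruth)
#' @rdname bilRscreen-accessors
#' @export
setMethod("fixtureSeed", "PangenomeFixture", function(x) x@seed)

#' @rdname bilRscreen-accessors
#' @export
setMethod("sequences", "BilrFamilyFixture", function(x) x@sequences)
#' @rdname bilRscreen-accessors
#' @export
setMethod("familyTruth", "BilrFamilyFixture", function(x) x@truth)
#' @rdname bilRscreen-accessors
#' @export
setMethod("motifTruth", "BilrFamilyFixture", function(x) x@motifTruth)
#' @rdname bilRscreen-accessors
#' @export
setMethod("domainTable", "BilrFamilyFixture", function(x) x@domainTable)
#' @rdname bilRscreen-accessors
#' @export
setMethod("decoyType", "BilrFamilyFixture", function(x) x@decoyType)
#' @rdname bilRscreen-accessors
#' @export
setMethod("familyAlignment", "BilrFamilyFixture", function(x) x@alignment)
#' @rdname bilRscreen-accessors
#' @export
setMethod("fixtureSeed", "BilrFamilyFixture", function(x) x@seed)

#' @rdname bilRscreen-accessors
#' @param sample sample identifier.
#' @export
setMethod("sampleReads", "MetagenomeFixture", function(x, sample) {
  if (missing(sample)) return(x@reads)
  if (!sample %in% names(x@reads)) stop("unknown sample: ", sample)
  x@reads[[sample]]
})
#' @rdname bilRscreen-accessors
#' @export
setMethod("sampleMeta", "MetagenomeFixture", function(x) x@meta)
#' @rdname bilRscreen-accessors
#' @export
setMethod("geneRefs", "MetagenomeFixture", function(x) x@geneRefs)
#' @rdname bilRscreen-accessors
#' @export
setMethod("hostRef", "MetagenomeFixture", function(x) x@hostRef)
#' @rdname bilRscreen-accessors
#' @export
setMethod("truthPresence", "MetagenomeFixture", function(x) x@truthPresence)
#' @rdname bilRscreen-accessors
#' @export
setMethod("truthGeneFraction", "MetagenomeFixture",
          function(x) x@truthGeneFraction)
#' @rdname bilRscreen-accessors
#' @export
setMethod("fixtureSeed", "MetagenomeFixture", function(x) x@seed)

#' @rdname bilRscreen-accessors
#' @export
setMethod("measurements", "FluorescenceFixture", function(x) x@measurements)
#' @rdname bilRscreen-accessors
#' @export
setMethod("controlValues", "FluorescenceFixture", function(x) x@control)
#' @rdname bilRscreen-accessors
#' @export
setMethod("truthReducer", "FluorescenceFixture", function(x) x@truthReducer)
#' @rdname bilRscreen-accessors
#' @export
setMethod("fixtureSeed", "FluorescenceFixture", function(x) x@seed)

#' @rdname bilRscreen-accessors
#' @export
setMethod("membership", "OrthogroupSet", function(x) x@membership)
#' @rdname bilRscreen-accessors
#' @export
setMethod("presenceMatrix", "OrthogroupSet", function(x) x@presence)
#' @rdname bilRscreen-accessors
#' @export
setMethod("groupIds", "OrthogroupSet", function(x) rownames(x@presence))
#' @rdname bilRscreen-accessors
#' @param group orthogroup identifier.
#' @export
setMethod("groupMembers", "OrthogroupSet", function(x, group) {
  m <- x@membership
  if (!group %in% m$group) stop("unknown group: ", group)
  m$protein[m$group == group]
})

#' @rdname bilRscreen-accessors
#' @export
setMethod("nMatchColumns", "ProfileHMM",
          function(x) nrow(x@matchEmissions))
#' @rdname bilRscreen-accessors
#' @export
setMethod("matchEmissions", "ProfileHMM", function(x) x@matchEmissions)
#' @rdname bilRscreen-accessors
#' @export
setMethod("motifColumns", "ProfileHMM", function(x) x@motifColumns)
#' @rdname bilRscreen-accessors
#' @export
setMethod("referenceLength", "ProfileHMM", function(x) x@referenceLength)
#' @rdname bilRscreen-accessors
#' @export
setMethod("isCalibrated", "ProfileHMM",
          function(x) !is.na(x@mu) && !is.na(x@lambda))
#' @rdname bilRscreen-accessors
#' @export
setMethod("gumbelParams", "ProfileHMM",
          function(x) c(mu = x@mu, lambda = x@lambda))

#' @rdname bilRscreen-accessors
#' @export
setMethod("hitScore", "HmmHit", function(x) x@score)
#' @rdname bilRscreen-accessors
#' @export
setMethod("hitEvalue", "HmmHit", function(x) x@evalue)
#' @rdname bilRscreen-accessors
#' @export
setMethod("hitRegion", "HmmHit", function(x) x@region)
#' @rdname bilRscreen-accessors
#' @export
setMethod("matchMap", "HmmHit", function(x) x@matchMap)

#' @rdname bilRscreen-accessors
#' @export
setMethod("verdict", "BilRCall", function(x) x@verdict)
#' @rdname bilRscreen-accessors
#' @export
setMethod("filterAudit", "BilRCall", function(x)
  c(evalue_pass = x@evaluePass, length_pass = x@lengthPass,
    motif_pass = x@motifPass, domain_pass = x@domainPass))

#' @rdname bilRscreen-accessors
#' @export
setMethod("candidates", "ScreenResult", function(x) x@candidates)
#' @rdname bilRscreen-accessors
#' @export
setMethod("screenAudit", "ScreenResult", function(x) x@audit)

setMethod("show", "PangenomeFixture", function(object) {
  ph <- table(object@phenotype)
  cat("PangenomeFixture:", length(object@proteomes), "strains (",
      ph[["reducer"]], "reducers ), ",
      length(unique(object@groupTruth)), "true orthogroups,",
      length(object@causalGroup), "planted causal proteins\n")
})

setMethod("show", "BilrFamilyFixture", function(object) {
  tb <- table(object@truth)
  cat("BilrFamilyFixture:", length(object@sequences), "proteins (",
      paste(names(tb), tb, collapse = ", "), ")\n")
})

setMethod("show", "MetagenomeFixture", function(object) {
  cat("MetagenomeFixture:", length(object@reads), "samples,",
      sum(lengths(object@reads)), "reads of length", object@readLength,
      "bp;", sum(object@truthPresence), "bilR-positive by truth\n")
})

setMethod("show", "FluorescenceFixture", function(object) {
  cat("FluorescenceFixture:", length(object@measurements), "strains,",
      sum(object@truthReducer), "planted reducers,",
      length(object@control), "control replicates\n")
})

setMethod("show", "OrthogroupSet", function(object) {
  cat("OrthogroupSet:", nrow(object@presence), "groups over",
      ncol(object@presence), "strains (",
      nrow(object@membership), "proteins )\n")
})

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM:", nrow(object@matchEmissions), "match columns;",
      "motif columns", paste(object@motifColumns, collapse = "-"),
      "; reference length", object@referenceLength, "\n")
  if (isCalibrated(object))
    cat("  calibrated: Gumbel mu =", signif(object@mu, 4),
        ", lambda =", signif(object@lambda, 4), "\n")
  else cat("  not calibrated\n")
})

setMethod("show", "HmmHit", function(object) {
  cat("HmmHit", object@targetId, ": score", signif(object@score, 5),
      "bits; region", object@region[1], "-", object@region[2],
      if (!is.na(object@evalue)) paste("; E =", signif(object@evalue, 3))
      else "", "\n")
})

setMethod("show", "BilRCall", function(object) {
  a <- filterAudit(object)
  cat("BilRCall", object@targetId, ": verdict", object@verdict, "[",
      paste(names(a)[!a], collapse = ","), "]\n")
})

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult (", object@mode, "):",
      length(object@candidates), "candidate group(s) of",
      nrow(object@audit), "\n")
})

setMethod("show", "PrevalenceResult", function(object) {
  cat("PrevalenceResult:", object@groups[1], sprintf("%d/%d", object@absent[1],
      object@n[1]), "absent vs", object@groups[2],
      sprintf("%d/%d", object@absent[2], object@n[2]),
      "; X2 =", signif(object@statistic, 4),
      ", p =", signif(object@pValue, 3),
      if (object@correct) "(Yates)" else "", "\n")
})
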