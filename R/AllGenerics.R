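#' @include AllClasses.R
NULL

#' @name bilRscreen-accessors
#' @title Accessors for bilRscreen classes
#' @description Accessor generics for the fixture, orthogroup, profile-HMM
#'   and result classes. Slots are never reached into directly by user code.
#' @param x,object an object of the documented class.
#' @param ... ignored.
#' @return the corresponding slot value.
NULL

#' @rdname bilRscreen-accessors
#' @export
setGeneric("proteomes", function(x) standardGeneric("proteomes"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("ecTable", function(x) standardGeneric("ecTable"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("causalGroup", function(x) standardGeneric("causalGroup"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("groupTruth", function(x) standardGeneric("groupTruth"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("familyTruth", function(x) standardGeneric("familyTruth"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("motifTruth", function(x) standardGeneric("motifTruth"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("domainTable", function(x) standardGeneric("domainTable"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("decoyType", function(x) standardGeneric("decoyType"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("familyAlignment", function(x) standardGeneric("familyAlignment"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("sampleReads", function(x, sample) standardGeneric("sampleReads"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("geneRefs", function(x) standardGeneric("geneRefs"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("hostRef", function(x) standardGeneric("hostRef"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("truthPresence", function(x) standardGeneric("truthPresence"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("truthGeneFraction",
           function(x) standardGeneric("truthGeneFraction"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("controlValues", function(x) standardGeneric("controlValues"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("truthReducer", function(x) standardGeneric("truthReducer"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("groupMembers", function(x, group) standardGeneric("groupMembers"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("nMatchColumns", function(x) standardGeneric("nMatchColumns"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("matchEmissions", function(x) standardGeneric("matchEmissions"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("motifColumns", function(x) standardGeneric("motifColumns"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("referenceLength", function(x) standardGeneric("referenceLength"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("isCalibrated", function(x) standardGeneric("isCalibrated"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("gumbelParams", function(x) standardGeneric("gumbelParams"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("hitScore", function(x) standardGeneric("hitScore"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("hitEvalue", function(x) standardGeneric("hitEvalue"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("hitRegion", function(x) standardGeneric("hitRegion"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("matchMap", function(x) standardGeneric("matchMap"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("filterAudit", function(x) standardGeneric("filterAudit"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("screenAudit", function(x) standardGeneric("screenAudit"))
#' @rdname bilRscreen-accessors
#' @export
setGeneric("fixtureSeed", function(x) standardGeneric("fixtureSeed"))
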