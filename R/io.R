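#' @include config.R
NULL

#' Read / write FASTA
#'
#' Thin validating wrappers over [Biostrings::readAAStringSet()] and
#' friends: sequence ids are the first whitespace-delimited token of the
#' header, case is normalized to upper, duplicate ids and empty sequences
#' are errors. `writeFasta` / `readFasta` round-trip (id, sequence) pairs
#' exactly.
#'
#' @param path FASTA file path.
#' @param type "protein" or "dna".
#' @return an [Biostrings::AAStringSet] or [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  x <- if (type == "protein") Biostrings::readAAStringSet(path)
  else Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence id(s): ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (any(Biostrings::width(x) == 0L))
    stop("empty sequence: ",
         paste(names(x)[Biostrings::width(x) == 0L], collapse = ", "))
  ch <- toupper(as.character(x))
  if (type == "protein") Biostrings::AAStringSet(setNames(ch, names(x)))
  else Biostrings::DNAStringSet(setNames(ch, names(x)))
}

#' @rdname readFasta
#' @param x a named [Biostrings::XStringSet].
#' @export
writeFasta <- function(x, path) {
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("records must carry unique names")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write 4-line FASTQ
#'
#' Strict 4-line-record FASTQ: a truncated record or a sequence/quality
#' length mismatch is an error reporting the offending line number.
#' Gzipped input is read transparently; a `.gz` suffix on the output path
#' writes gzipped.
#'
#' @param path FASTQ path (optionally .gz).
#' @return `readFastq` returns a named [Biostrings::DNAStringSet] with the
#'   per-read quality strings in `attr(, "qualities")`.
#' @export
readFastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("truncated FASTQ record at line ", (n %/% 4L) * 4L + 1L)
  if (n == 0L) return(Biostrings::DNAStringSet())
  idL <- lines[seq(1L, n, 4L)]
  sq <- lines[seq(2L, n, 4L)]
  plus <- lines[seq(3L, n, 4L)]
  qual <- lines[seq(4L, n, 4L)]
  badId <- which(!startsWith(idL, "@"))
  if (length(badId))
    stop("malformed header at line ", (badId[1] - 1L) * 4L + 1L)
  badPlus <- which(!startsWith(plus, "+"))
  if (length(badPlus))
    stop("malformed separator at line ", (badPlus[1] - 1L) * 4L + 3L)
  badLen <- which(nchar(sq) != nchar(qual))
  if (length(badLen))
    stop("sequence/quality length mismatch at line ",
         (badLen[1] - 1L) * 4L + 4L)
  ids <- sub("\\s.*$", "", substring(idL, 2L))
  out <- Biostrings::DNAStringSet(setNames(toupper(sq), ids))
  attr(out, "qualities") <- qual
  out
}

#' @rdname readFastq
#' @param reads a named [Biostrings::DNAStringSet].
#' @param qualities per-read quality strings; default constant Phred 40.
#' @export
writeFastq <- function(reads, path, qualities = NULL) {
  ids <- names(reads)
  if (is.null(ids)) stop("reads must be named")
  sq <- as.character(reads)
  if (is.null(qualities)) qualities <- strrep("I", nchar(sq))
  if (any(nchar(qualities) != nchar(sq)))
    stop("quality strings must match sequence lengths")
  con <- if (endsWith(path, ".gz")) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", sq, "\n+\n", qualities), con)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read pipeline fixtures on disk
#'
#' Fixtures serialize to the pipeline's external formats — per-strain
#' proteome FASTA, gene/host reference FASTA, 4-line FASTQ read sets, and
#' tab-separated phenotype/EC/domain/metadata/fluorescence tables — with
#' the recorded ground truth in a `truth.json` sidecar. Each reader
#' reconstructs a fixture equal to the one written.
#'
#' @param fixture the fixture object.
#' @param dir directory to write to (created if needed).
#' @return the writer returns `dir` invisibly; the reader the fixture.
#' @name fixture-io
NULL

#' @rdname fixture-io
#' @export
writePangenome <- function(fixture, dir) {
  stopifnot(is(fixture, "PangenomeFixture"))
  dir.create(file.path(dir, "proteomes"), recursive = TRUE,
             showWarnings = FALSE)
  for (s in names(proteomes(fixture)))
    writeFasta(proteomes(fixture)[[s]],
               file.path(dir, "proteomes", paste0(s, ".faa")))
  writeTsv(data.frame(strain = names(phenotype(fixture)),
                      label = unname(phenotype(fixture))),
           file.path(dir, "phenotype.tsv"))
  writeTsv(data.frame(protein = names(ecTable(fixture)),
                      ec = unname(ecTable(fixture))),
           file.path(dir, "ec.tsv"))
  jsonlite::write_json(
    list(groupTruth = as.list(groupTruth(fixture)),
         causalGroup = causalGroup(fixture),
         seed = fixture@seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname fixture-io
#' @export
readPangenome <- function(dir) {
  files <- sort(list.files(file.path(dir, "proteomes"), "\\.faa$",
                           full.names = TRUE))
  prot <- lapply(files, readFasta, type = "protein")
  names(prot) <- sub("\\.faa$", "", basename(files))
  ph <- readTsv(file.path(dir, "phenotype.tsv"))
  ec <- readTsv(file.path(dir, "ec.tsv"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  new("PangenomeFixture", proteomes = prot,
      phenotype = setNames(ph$label, ph$strain),
      ecTable = setNames(as.character(ec$ec), ec$protein),
      groupTruth = unlist(tr$groupTruth),
      causalGroup = as.character(unlist(tr$causalGroup)),
      seed = as.integer(tr$seed))
}

#' @rdname fixture-io
#' @export
writeBilrFamily <- function(fixture, dir) {
  stopifnot(is(fixture, "BilrFamilyFixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeFasta(sequences(fixture), file.path(dir, "sequences.faa"))
  writeFasta(familyAlignment(fixture), file.path(dir, "alignment.afa"))
  dt <- domainTable(fixture)
  writeTsv(data.frame(protein = names(dt),
                      domains = vapply(dt, paste, character(1),
                                       collapse = ",")),
           file.path(dir, "domains.tsv"))
  jsonlite::write_json(
    list(truth = as.list(familyTruth(fixture)),
         motifTruth = as.list(motifTruth(fixture)),
         decoyType = as.list(decoyType(fixture)),
         referenceId = fixture@referenceId,
         motifStart = fixture@motifStart, seed = fixture@seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname fixture-io
#' @export
readBilrFamily <- function(dir) {
  dom <- readTsv(file.path(dir, "domains.tsv"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  new("BilrFamilyFixture",
      sequences = readFasta(file.path(dir, "sequences.faa")),
      truth = unlist(tr$truth),
      motifTruth = unlist(tr$motifTruth),
      domainTable = setNames(strsplit(dom$domains, ",", fixed = TRUE),
                             dom$protein),
      decoyType = if (length(tr$decoyType)) unlist(tr$decoyType)
                  else setNames(character(0), character(0)),
      alignment = readFasta(file.path(dir, "alignment.afa")),
      referenceId = tr$referenceId,
      motifStart = as.integer(tr$motifStart), seed = as.integer(tr$seed))
}

#' @rdname fixture-io
#' @export
writeMetagenome <- function(fixture, dir) {
  stopifnot(is(fixture, "MetagenomeFixture"))
  dir.create(file.path(dir, "reads"), recursive = TRUE,
             showWarnings = FALSE)
  for (s in names(sampleReads(fixture)))
    writeFastq(sampleReads(fixture, s),
               file.path(dir, "reads", paste0(s, ".fastq")))
  writeFasta(geneRefs(fixture), file.path(dir, "bilr_refs.fa"))
  writeFasta(hostRef(fixture), file.path(dir, "host.fa"))
  writeTsv(sampleMeta(fixture), file.path(dir, "metadata.tsv"))
  jsonlite::write_json(
    list(truthGeneFraction = as.list(truthGeneFraction(fixture)),
         readLength = fixture@readLength, errorRate = fixture@errorRate,
         seed = fixture@seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname fixture-io
#' @export
readMetagenome <- function(dir) {
  files <- sort(list.files(file.path(dir, "reads"), "\\.fastq(\\.gz)?$",
                           full.names = TRUE))
  reads <- lapply(files, readFastq)
  for (i in seq_along(reads)) attr(reads[[i]], "qualities") <- NULL
  names(reads) <- sub("\\.fastq(\\.gz)?$", "", basename(files))
  meta <- readTsv(file.path(dir, "metadata.tsv"))
  meta$ageDays <- as.integer(meta$ageDays)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  gf <- unlist(tr$truthGeneFraction)
  new("MetagenomeFixture", reads = reads, meta = meta,
      geneRefs = readFasta(file.path(dir, "bilr_refs.fa"), type = "dna"),
      hostRef = readFasta(file.path(dir, "host.fa"), type = "dna"),
      truthPresence = gf > 0, truthGeneFraction = gf,
      readLength = as.integer(tr$readLength),
      errorRate = as.numeric(tr$errorRate), seed = as.integer(tr$seed))
}

#' @rdname fixture-io
#' @export
writeFluorescence <- function(fixture, dir) {
  stopifnot(is(fixture, "FluorescenceFixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meas <- measurements(fixture)
  tab <- rbind(
    do.call(rbind, lapply(names(meas), function(s)
      data.frame(strain = s, replicate = seq_along(meas[[s]]),
                 value = meas[[s]]))),
    data.frame(strain = "control",
               replicate = seq_along(controlValues(fixture)),
               value = controlValues(fixture)))
  write.table(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
              file.path(dir, "fluorescence.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(truthReducer = as.list(truthReducer(fixture)),
         seed = fixture@seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname fixture-io
#' @export
readFluorescence <- function(dir) {
  tab <- readTsv(file.path(dir, "fluorescence.tsv"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  ctrl <- tab$value[tab$strain == "control"]
  keep <- tab$strain != "control"
  new("FluorescenceFixture",
      measurements = split(tab$value[keep], tab$strain[keep]),
      control = ctrl,
      truthReducer = unlist(tr$truthReducer),
      seed = as.integer(tr$seed))
}
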