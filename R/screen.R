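#' @include config.R
NULL

#' Local protein alignment score
#'
#' Smith-Waterman local alignment score with affine gaps (BLOSUM62, gap
#' open 11, gap extend 1 by default; a gap of length g costs
#' `gapOpen + g * gapExtend`). Used as the homology score behind
#' reciprocal-best-hit orthogroup clustering. Scoring is delegated to
#' [Biostrings::pairwiseAlignment()].
#'
#' @param a character vector of query protein sequences.
#' @param b a single subject protein sequence.
#' @param matrix substitution matrix name (see [Biostrings::pairwiseAlignment()]).
#' @param gapOpen,gapExtend positive gap penalties.
#' @param mask if FALSE (default) residues outside the 20 canonical amino
#'   acids are an error; if TRUE they are replaced by "X" and scored by the
#'   matrix's X column.
#' @return numeric vector of scores, one per query.
#' @examples
#' alignScore("ACDEFGHIK", "ACDEFGHIK")
#' @export
alignScore <- function(a, b, matrix = "BLOSUM62", gapOpen = 11,
                       gapExtend = 1, mask = FALSE) {
  if (!length(a) || !nzchar(b)) stop("sequences must be non-empty")
  bad <- grepl(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")),
               c(a, b))
  if (any(bad)) {
    if (!mask) stop("unknown residue in input sequence")
    pat <- sprintf("[^%s]", paste(AA_STANDARD, collapse = ""))
    a <- gsub(pat, "X", a)
    b <- gsub(pat, "X", b)
  }
  as.numeric(Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = matrix, gapOpening = gapOpen,
    gapExtension = gapExtend, scoreOnly = TRUE))
}

# self-score of a local alignment: with a positive-diagonal matrix the
# optimal self alignment is the full ungapped diagonal
selfScore <- function(seqs, matrix = "BLOSUM62") {
  mat <- getSubMatrix(matrix)
  d <- diag(mat)[AA_STANDARD]
  vapply(strsplit(seqs, "", fixed = TRUE), function(ch)
    sum(d[ch]), numeric(1))
}

getSubMatrix <- function(name) {
  if (is.matrix(name)) return(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

# candidate homolog pairs by shared k-mers (alignment prefilter); returns a
# 2-column index matrix into `seqs`
sharedKmerPairs <- function(seqs, k = 5L, minShared = 2L) {
  km <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  owner <- rep(seq_along(seqs), lengths(km))
  byKmer <- split(owner, unlist(km, use.names = FALSE))
  byKmer <- byKmer[lengths(byKmer) >= 2L]
  if (!length(byKmer)) return(matrix(integer(0), 0, 2))
  pairs <- do.call(rbind, lapply(byKmer, function(v) {
    v <- sort(unique(v))
    if (length(v) < 2L) return(NULL)
    t(combn(v, 2L))
  }))
  if (is.null(pairs)) return(matrix(integer(0), 0, 2))
  key <- paste(pairs[, 1], pairs[, 2])
  cnt <- table(key)
  keep <- names(cnt)[cnt >= minShared]
  m <- matrix(as.integer(unlist(strsplit(keep, " ", fixed = TRUE))),
              ncol = 2, byrow = TRUE)
  m
}

makeOrthogroupSet <- function(membership, strains = unique(membership$strain)) {
  groups <- sort(unique(membership$group))
  pres <- matrix(FALSE, length(groups), length(strains),
                 dimnames = list(groups, strains))
  idx <- cbind(match(membership$group, groups),
               match(membership$strain, strains))
  pres[idx] <- TRUE
  new("OrthogroupSet", membership = membership, presence = pres)
}

#' Cluster proteomes into orthogroups by reciprocal best hits
#'
#' A transparent stand-in for dedicated orthology pipelines with the same
#' output contract: for every pair of strains, each protein's best-scoring
#' cross-strain partner (local BLOSUM62 score at least `minScoreRatio`
#' times the query's self-score; ties broken by lexicographic protein id)
#' defines a hit, reciprocal best hits define edges, and the connected
#' components of the resulting graph are the orthogroups. Every protein
#' belongs to exactly one group; proteins with no cross-strain hit become
#' singletons. A shared-k-mer prefilter keeps the number of alignments
#' computed proportional to the number of genuinely homologous pairs.
#'
#' @param proteomes named list of [Biostrings::AAStringSet], one per
#'   strain, or a [PangenomeFixture-class].
#' @param minScoreRatio hit acceptance threshold relative to self-score.
#' @param config a [BilrConfig-class] supplying alignment parameters.
#' @return an [OrthogroupSet-class]; group ids are assigned in order of
#'   each group's lexicographically smallest member so the result is
#'   invariant to strain and protein input order.
#' @export
clusterOrthogroups <- function(proteomes, config = bilrConfig(),
                               minScoreRatio = config@minScoreRatio) {
  if (is(proteomes, "PangenomeFixture")) proteomes <- proteomes(proteomes)
  if (length(proteomes) < 2L) stop("need proteomes from >= 2 strains")
  if (any(lengths(proteomes) == 0L)) stop("empty proteome")

  ids <- unlist(lapply(proteomes, names), use.names = FALSE)
  strainOf <- rep(names(proteomes), lengths(proteomes))
  seqs <- unlist(lapply(proteomes, as.character), use.names = FALSE)
  ord <- order(ids)   # canonical processing order
  ids <- ids[ord]; strainOf <- strainOf[ord]; seqs <- seqs[ord]
  self <- selfScore(seqs)

  cand <- sharedKmerPairs(seqs)
  if (nrow(cand)) {
    cross <- strainOf[cand[, 1]] != strainOf[cand[, 2]]
    cand <- cand[cross, , drop = FALSE]
  }
  scores <- numeric(nrow(cand))
  if (nrow(cand)) {
    bySubj <- split(seq_len(nrow(cand)), cand[, 2])
    for (rows in bySubj) {
      j <- cand[rows[1], 2]
      scores[rows] <- alignScore(seqs[cand[rows, 1]], seqs[j],
                                 gapOpen = config@gapOpen,
                                 gapExtend = config@gapExtend)
    }
  }

  # best cross-strain partner per (protein, partner strain)
  hit <- new.env(parent = emptyenv())
  noteHit <- function(q, t, s) {
    thr <- minScoreRatio * self[q]
    if (s < thr) return()
    key <- paste0(q, "|", strainOf[t])
    cur <- get0(key, envir = hit)
    if (is.null(cur) || s > cur$s ||
        (s == cur$s && ids[t] < ids[cur$t]))
      assign(key, list(t = t, s = s), envir = hit)
  }
  for (r in seq_len(nrow(cand))) {
    noteHit(cand[r, 1], cand[r, 2], scores[r])
    noteHit(cand[r, 2], cand[r, 1], scores[r])
  }
  edgeList <- vector("list", length(ids))
  for (q in seq_along(ids)) {
    acc <- character(0)
    for (ts in setdiff(unique(strainOf), strainOf[q])) {
      h <- get0(paste0(q, "|", ts), envir = hit)
      if (is.null(h)) next
      back <- get0(paste0(h$t, "|", strainOf[q]), envir = hit)
      if (!is.null(back) && back$t == q && q < h$t)
        acc <- c(acc, ids[q], ids[h$t])
    }
    edgeList[[q]] <- acc
  }
  edges <- matrix(unlist(edgeList, use.names = FALSE), ncol = 2,
                  byrow = TRUE)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(ids)
  if (nrow(edges)) g <- igraph::add_edges(g, as.vector(t(edges)))
  comp <- igraph::components(g)$membership
  # canonical group ids: order components by smallest member id
  first <- tapply(names(comp), comp, min)
  rank <- match(comp, as.integer(names(sort(first))))
  gid <- sprintf("CL%04d", rank)
  makeOrthogroupSet(
    data.frame(protein = ids, strain = strainOf,
               group = gid[match(ids, names(comp))],
               stringsAsFactors = FALSE),
    strains = sort(names(proteomes)))
}

# first EC field, NA for unannotated/malformed (malformed warns)
ecClassOf <- function(ec) {
  ok <- grepl("^[0-9]+(\\.([0-9]+|-|n[0-9]*)){3}$", ec)
  if (any(!ok & !is.na(ec)))
    warning("malformed EC string(s) treated as unannotated: ",
            paste(unique(ec[!ok & !is.na(ec)]), collapse = ", "))
  out <- rep(NA_character_, length(ec))
  out[ok] <- sub("\\..*$", "", ec[ok])
  out
}

# per-group count of members annotated with an EC in class 1
ecClass1Counts <- function(og, ec) {
  m <- membership(og)
  cls <- ecClassOf(unname(ec[m$protein]))
  cnt <- tapply(cls == "1" & !is.na(cls), m$group, sum)
  setNames(as.integer(cnt), names(cnt))[groupIds(og)]
}

#' Keep orthogroups annotated as oxidoreductases
#'
#' Retains groups with at least `minMembers` (default 3, i.e. "more than
#' 2") members whose EC annotation falls in class 1 (EC 1.-.-.-, the
#' oxidoreductases); matching is by EC class prefix. Under
#' `allMembers = TRUE` the alternative reading is applied: the group must
#' have more than `minMembers - 1` members and every member must carry a
#' class-1 annotation. Malformed EC strings warn and count as unannotated.
#'
#' @param og an [OrthogroupSet-class].
#' @param ec named character vector mapping protein ids to EC strings.
#' @param config a [BilrConfig-class].
#' @param minMembers,allMembers see above.
#' @return the filtered [OrthogroupSet-class].
#' @export
filterOxidoreductase <- function(og, ec, config = bilrConfig(),
                                 minMembers = config@ecMinMembers,
                                 allMembers = config@ecAllMembers) {
  cnt <- ecClass1Counts(og, ec)
  size <- table(membership(og)$group)[groupIds(og)]
  keep <- if (allMembers)
    groupIds(og)[cnt == size & size >= minMembers]
  else
    groupIds(og)[cnt >= minMembers]
  subsetGroups(og, keep)
}

subsetGroups <- function(og, groups) {
  m <- membership(og)
  m <- m[m$group %in% groups, , drop = FALSE]
  rownames(m) <- NULL
  new("OrthogroupSet", membership = m,
      presence = og@presence[groups, , drop = FALSE])
}

#' Screen orthogroup presence patterns against the reducer phenotype
#'
#' Strict mode returns the groups present in every reducer strain and
#' absent from every non-reducer strain. Scored mode ranks all groups by
#' the Hamming distance between their strain presence vector and the
#' phenotype indicator (distance 0 is exactly the strict match).
#'
#' @param og an [OrthogroupSet-class].
#' @param phenotype named character ("reducer"/"non_reducer") covering
#'   every strain in `og`; at least one of each phenotype is required.
#' @param mode "strict" or "scored".
#' @return a [ScreenResult-class] whose audit has one row per group with
#'   its Hamming distance and pattern outcome.
#' @export
phenotypePatternScreen <- function(og, phenotype,
                                   mode = c("strict", "scored")) {
  mode <- match.arg(mode)
  pres <- presenceMatrix(og)
  strains <- colnames(pres)
  if (!all(strains %in% names(phenotype)))
    stop("phenotype missing for strain(s): ",
         paste(setdiff(strains, names(phenotype)), collapse = ", "))
  ph <- phenotype[strains] == "reducer"
  if (!any(ph) || all(ph))
    stop("need at least one reducer and one non-reducer strain")
  ham <- as.integer(rowSums(pres != matrix(ph, nrow(pres), length(ph),
                                           byrow = TRUE)))
  audit <- data.frame(group = rownames(pres), hamming = ham,
                      patternPass = ham == 0L,
                      candidate = ham == 0L,
                      stringsAsFactors = FALSE)
  if (mode == "scored") audit <- audit[order(audit$hamming, audit$group), ]
  rownames(audit) <- NULL
  new("ScreenResult", candidates = audit$group[audit$candidate],
      audit = audit, phenotype = phenotype, mode = mode)
}

#' Phenotype-guided candidate screen (oxidoreductase filter + pattern match)
#'
#' The discovery screen as a whole: orthogroups are first filtered to
#' putative oxidoreductases (class-1 EC annotation on at least
#' `ecMinMembers` members) and the survivors' presence patterns are matched
#' against the reducer phenotype. Candidates are the groups passing both
#' filters; the audit records both outcomes for every input group. The two
#' filters are pure and act on disjoint criteria, so their order does not
#' affect the candidate set.
#'
#' @param og an [OrthogroupSet-class].
#' @param ec named character EC table.
#' @param phenotype named strain phenotype vector.
#' @param config a [BilrConfig-class].
#' @param mode "strict" or "scored" (see [phenotypePatternScreen()]).
#' @return a [ScreenResult-class].
#' @export
screenCandidates <- function(og, ec, phenotype, config = bilrConfig(),
                             mode = c("strict", "scored")) {
  mode <- match.arg(mode)
  cnt <- ecClass1Counts(og, ec)
  oxo <- filterOxidoreductase(og, ec, config)
  pat <- phenotypePatternScreen(og, phenotype, mode = mode)
  audit <- screenAudit(pat)
  audit$ecClass1Members <- unname(cnt[audit$group])
  audit$ecPass <- audit$group %in% groupIds(oxo)
  audit$candidate <- audit$ecPass & audit$patternPass
  new("ScreenResult", candidates = audit$group[audit$candidate],
      audit = audit, phenotype = phenotype, mode = mode)
}
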