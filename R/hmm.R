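#' @include config.R
NULL

encodeAA <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(ch, AA_STANDARD)
  if (anyNA(code))
    stop("sequence contains residues outside the 20-letter alphabet: ",
         paste(unique(ch[is.na(code)]), collapse = ""))
  code
}

#' Build a profile HMM from a clade alignment
#'
#' Restricts the alignment to the columns where the reference sequence has
#' a residue inside `referenceSpan` (for the BilR study: the columns
#' matching the first 373 residues of the reference protein, i.e. its TIM
#' barrel). Among those, columns with more than `maxGapFraction` gaps are
#' demoted to insert columns. Match emissions are Laplace
#' (add-`pseudocount`) estimates over the 20-residue alphabet; transition
#' probabilities are counted from the alignment's gap structure with
#' add-one pseudocounts (Plan-7 state set, no I<->D transitions). The four
#' consecutive motif residue positions on the reference are mapped to
#' match-column indices; a motif position falling in a demoted column is a
#' build error, since motif detection is by column homology.
#'
#' @param msa aligned sequences ([Biostrings::AAStringSet], equal widths,
#'   gaps as "-").
#' @param referenceId name of the reference row.
#' @param motifReferencePositions integer(4), consecutive residue positions
#'   of the conserved motif on the (degapped) reference.
#' @param referenceSpan integer(2) 1-based inclusive residue range of the
#'   reference to model; default the whole reference.
#' @param maxGapFraction columns with a greater gap fraction become inserts.
#' @param pseudocount Dirichlet pseudocount added per residue.
#' @param background residue background distribution (default uniform).
#' @param referenceLength protein length used by the 50%-length filter;
#'   defaults to the full degapped reference length. An explicit field so
#'   the filter's reference protein is never hard-coded.
#' @return an uncalibrated [ProfileHMM-class].
#' @export
buildProfile <- function(msa, referenceId, motifReferencePositions,
                         referenceSpan = NULL, maxGapFraction = 0.5,
                         pseudocount = 1, background = rep(1 / 20, 20),
                         referenceLength = NULL) {
  if (!is(msa, "AAStringSet")) msa <- Biostrings::AAStringSet(msa)
  if (length(unique(Biostrings::width(msa))) != 1L)
    stop("alignment rows must have equal width")
  if (!referenceId %in% names(msa))
    stop("reference '", referenceId, "' not in alignment")
  rows <- strsplit(toupper(as.character(msa)), "", fixed = TRUE)
  ref <- rows[[referenceId]]
  isGap <- function(x) x %in% c("-", ".")
  refCols <- which(!isGap(ref))
  refLenFull <- length(refCols)
  if (is.null(referenceSpan)) referenceSpan <- c(1L, refLenFull)
  if (referenceSpan[1] < 1L || referenceSpan[2] > refLenFull ||
      referenceSpan[1] > referenceSpan[2])
    stop("'referenceSpan' outside the reference length")
  mp <- as.integer(motifReferencePositions)
  if (length(mp) != 4L || !all(diff(mp) == 1L))
    stop("'motifReferencePositions' must be 4 consecutive positions")
  if (mp[1] < referenceSpan[1] || mp[4] > referenceSpan[2])
    stop("motif positions must lie inside 'referenceSpan'")

  candCols <- refCols[referenceSpan[1]:referenceSpan[2]]
  alnMat <- do.call(rbind, rows)
  gapFrac <- colMeans(matrix(isGap(alnMat[, candCols]),
                             nrow = nrow(alnMat)))
  matchCols <- candCols[gapFrac <= maxGapFraction]
  L <- length(matchCols)
  if (L < 1L) stop("no match columns survive the gap-fraction rule")
  motifCols <- match(refCols[mp], matchCols)
  if (anyNA(motifCols))
    stop("a motif position lands in a non-match column; ",
         "motif columns must stay below the gap-fraction limit")

  emis <- matrix(0, L, 20, dimnames = list(NULL, AA_STANDARD))
  for (j in seq_len(L)) {
    col <- alnMat[, matchCols[j]]
    col <- col[!isGap(col)]
    bad <- setdiff(col, AA_STANDARD)
    if (length(bad)) stop("non-standard residue in alignment: ",
                          paste(bad, collapse = ""))
    cnt <- table(factor(col, levels = AA_STANDARD))
    emis[j, ] <- (as.numeric(cnt) + pseudocount) /
      (length(col) + 20 * pseudocount)
  }

  # transition counts from the gap structure between adjacent match columns
  cMM <- cMI <- cMD <- cII <- cIM <- cDD <- cDM <- rep(0, L)
  for (r in seq_len(nrow(alnMat))) {
    st <- ifelse(isGap(alnMat[r, matchCols]), "D", "M")
    for (j in seq_len(L - 1L)) {
      between <- if (matchCols[j + 1L] - matchCols[j] > 1L)
        sum(!isGap(alnMat[r, (matchCols[j] + 1L):(matchCols[j + 1L] - 1L)]))
      else 0L
      a <- st[j]; b <- st[j + 1L]
      if (between > 0L && a == "M") {
        cMI[j] <- cMI[j] + 1
        cII[j] <- cII[j] + between - 1L
        if (b == "M") cIM[j] <- cIM[j] + 1
      } else {
        if (a == "M" && b == "M") cMM[j] <- cMM[j] + 1
        if (a == "M" && b == "D") cMD[j] <- cMD[j] + 1
        if (a == "D" && b == "M") cDM[j] <- cDM[j] + 1
        if (a == "D" && b == "D") cDD[j] <- cDD[j] + 1
      }
    }
  }
  outM <- cMM + cMI + cMD + 3
  outI <- cII + cIM + 2
  outD <- cDD + cDM + 2
  transitions <- list(MM = (cMM + 1) / outM, MI = (cMI + 1) / outM,
                      MD = (cMD + 1) / outM, II = (cII + 1) / outI,
                      IM = (cIM + 1) / outI, DD = (cDD + 1) / outD,
                      DM = (cDM + 1) / outD)

  new("ProfileHMM", matchEmissions = emis,
      insertEmissions = background, transitions = transitions,
      background = background, motifColumns = as.integer(motifCols),
      referenceLength = as.integer(
        if (is.null(referenceLength)) refLenFull else referenceLength),
      mu = NA_real_, lambda = NA_real_)
}

# log2-odds emission matrix and log2 transition scores
profileScores <- function(profile) {
  em <- log2(sweep(profile@matchEmissions, 2, profile@background, "/"))
  tr <- lapply(profile@transitions, log2)
  list(emis = em, trans = tr)
}

#' Local Viterbi search of a target sequence
#'
#' Maximum-log-odds local alignment of the target against the profile,
#' Smith-Waterman style: entry into and exit from any match state is free,
#' insert states emit at the background (log-odds 0) and delete states are
#' silent; transitions are scored inside the aligned region. The score is
#' in bits. The returned hit carries the map from every profile match
#' column to the aligned target position (used for column-anchored motif
#' detection).
#'
#' @param profile a [ProfileHMM-class].
#' @param target protein sequence (character) over the 20-letter alphabet.
#' @param id target identifier stored in the hit.
#' @return an [HmmHit-class] without an E-value.
#' @export
viterbiSearch <- function(profile, target, id = "target") {
  stopifnot(is(profile, "ProfileHMM"))
  if (!is.character(target)) target <- as.character(target)
  if (!nzchar(target)) stop("target sequence is empty")
  sc <- profileScores(profile)
  res <- viterbi_core(sc$emis, sc$trans, encodeAA(target))
  new("HmmHit", targetId = id, score = res$score, evalue = NA_real_,
      region = c(res$tstart, res$tend), matchMap = res$matchMap)
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits location and scale of a Gumbel (type-I extreme value) distribution
#' by maximum likelihood: moment estimates
#' (`lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma / lambda`) seed a
#' BFGS optimization of the exact log-likelihood.
#'
#' @param x numeric sample.
#' @return named numeric `c(mu, lambda)`.
#' @export
fitGumbel <- function(x) {
  if (length(x) < 10) stop("need >= 10 observations")
  s <- sd(x)
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate score distribution: zero variance")
  lam0 <- pi / (s * sqrt(6))
  mu0 <- mean(x) - 0.5772156649 / lam0
  nll <- function(p) {
    lam <- exp(p[2])
    z <- lam * (x - p[1])
    -(length(x) * p[2] - sum(z) - sum(exp(-z)))
  }
  fit <- optim(c(mu0, log(lam0)), nll, method = "BFGS")
  c(mu = fit$par[1], lambda = exp(fit$par[2]))
}

#' Calibrate a profile's E-value parameters
#'
#' Scores `nRandom` i.i.d. background-model sequences of length
#' `randomLength` with the local Viterbi search and fits a Gumbel
#' distribution to the null scores by maximum likelihood. Deterministic
#' for a fixed seed.
#'
#' @param profile a [ProfileHMM-class].
#' @param nRandom number of background sequences (>= 200).
#' @param randomLength their residue length.
#' @param seed RNG seed.
#' @return the profile with Gumbel `mu` and `lambda` set.
#' @export
calibrate <- function(profile, nRandom = 500L, randomLength = 150L, seed = 1L) {
  stopifnot(is(profile, "ProfileHMM"))
  if (nRandom < 200) stop("'nRandom' must be >= 200")
  sc <- profileScores(profile)
  scores <- withSeed(seed, {
    targets <- lapply(seq_len(nRandom), function(i)
      sample.int(20L, randomLength, replace = TRUE,
                 prob = profile@background))
    viterbi_scores(sc$emis, sc$trans, targets)
  })
  g <- fitGumbel(scores)
  profile@mu <- unname(g["mu"])
  profile@lambda <- unname(g["lambda"])
  validObject(profile)
  profile
}

#' Serialize / restore a profile HMM as JSON
#'
#' The JSON document carries the match emission matrix (rows = match
#' columns, residue order as in the `residues` field), the insert/
#' background emission vectors, the seven per-column transition vectors,
#' the motif column indices, the reference length and, when calibrated,
#' the Gumbel parameters. Numbers are written at full precision, so the
#' round-trip reconstructs the profile exactly.
#'
#' @param profile a [ProfileHMM-class].
#' @param path JSON file path.
#' @return `readProfileHMM` the profile; `writeProfileHMM` the path,
#'   invisibly.
#' @export
writeProfileHMM <- function(profile, path) {
  stopifnot(is(profile, "ProfileHMM"))
  jsonlite::write_json(list(
    residues = AA_STANDARD,
    matchEmissions = unname(apply(profile@matchEmissions, 1, identity,
                                  simplify = FALSE)),
    insertEmissions = profile@insertEmissions,
    background = profile@background,
    transitions = profile@transitions,
    motifColumns = profile@motifColumns,
    referenceLength = profile@referenceLength,
    mu = profile@mu, lambda = profile@lambda),
    path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeProfileHMM
#' @export
readProfileHMM <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  em <- if (is.matrix(x$matchEmissions)) x$matchEmissions
  else do.call(rbind, x$matchEmissions)
  colnames(em) <- x$residues
  toNum <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  new("ProfileHMM", matchEmissions = em[, AA_STANDARD, drop = FALSE],
      insertEmissions = as.numeric(x$insertEmissions),
      transitions = lapply(x$transitions, as.numeric),
      background = as.numeric(x$background),
      motifColumns = as.integer(x$motifColumns),
      referenceLength = as.integer(x$referenceLength),
      mu = toNum(x$mu), lambda = toNum(x$lambda))
}

#' Convert a bit score to an E-value
#'
#' Under the calibrated Gumbel null, the expected number of hits at or
#' above `score` in a database of `databaseSize` sequences:
#' `E = databaseSize * (1 - exp(-exp(-lambda * (score - mu))))`.
#'
#' @param score numeric bit score(s).
#' @param profile a calibrated [ProfileHMM-class].
#' @param databaseSize number of target sequences searched (>= 1).
#' @return numeric E-value(s), monotone decreasing in score.
#' @export
scoreToEvalue <- function(score, profile, databaseSize) {
  stopifnot(is(profile, "ProfileHMM"))
  if (!isCalibrated(profile))
    stop("profile is not calibrated; run calibrate() first")
  if (databaseSize < 1) stop("'databaseSize' must be >= 1")
  databaseSize * (1 - exp(-exp(-profile@lambda * (score - profile@mu))))
}
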