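# Independent oracles, deliberately written against the textbook
# definitions rather than the package's code paths.

# quadratic-space affine-gap local alignment DP; a gap of length g costs
# open + g * extend (matching the alignment function's convention)
swOracle <- function(a, b, open = 11, extend = 1, matName = "BLOSUM62") {
  e <- new.env()
  utils::data(list = matName, package = "Biostrings", envir = e)
  mat <- get(matName, envir = e)
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- E <- F <- matrix(0, n + 1, m + 1)
  E[] <- F[] <- -Inf
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(E[i + 1, j] - extend,
                             H[i + 1, j] - open - extend)
      F[i + 1, j + 1] <- max(F[i, j + 1] - extend,
                             H[i, j + 1] - open - extend)
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + mat[A[i], B[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# exhaustive enumeration of all local Plan-7 paths (entry/exit at match
# states, free flanks); exact reference for small profiles and targets
viterbiOracle <- function(emis, trans, target) {
  L <- nrow(emis); n <- length(target)
  tM <- lapply(trans, log2)
  best <- 0
  recur <- function(state, k, i, score) {
    if (state == "M") best <<- max(best, score)
    if (state == "M") {
      if (k < L && i < n)
        recur("M", k + 1, i + 1,
              score + tM$MM[k] + emis[k + 1, target[i + 1]])
      if (k < L)
        recur("D", k + 1, i, score + tM$MD[k])
      if (i < n)
        recur("I", k, i + 1, score + tM$MI[k])
    } else if (state == "I") {
      if (i < n) recur("I", k, i + 1, score + tM$II[k])
      if (k < L && i < n)
        recur("M", k + 1, i + 1,
              score + tM$IM[k] + emis[k + 1, target[i + 1]])
    } else {  # D
      if (k < L) recur("D", k + 1, i, score + tM$DD[k])
      if (k < L && i < n)
        recur("M", k + 1, i + 1,
              score + tM$DM[k] + emis[k + 1, target[i + 1]])
    }
  }
  for (i0 in seq_len(n))
    for (k0 in seq_len(L))
      recur("M", k0, i0, emis[k0, target[i0]])
  best
}

# a random valid ProfileHMM with L match columns (for oracle comparisons)
randomProfile <- function(L, seed) {
  set.seed(seed)
  em <- matrix(rgamma(L * 20, 0.5), L, 20)
  em <- em / rowSums(em)
  colnames(em) <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  rnd <- function(k) { x <- matrix(rgamma(L * k, 1), L, k); x / rowSums(x) }
  m3 <- rnd(3); i2 <- rnd(2); d2 <- rnd(2)
  tr <- list(MM = m3[, 1], MI = m3[, 2], MD = m3[, 3],
             II = i2[, 1], IM = i2[, 2], DD = d2[, 1], DM = d2[, 2])
  new("ProfileHMM", matchEmissions = em,
      insertEmissions = rep(1 / 20, 20), transitions = tr,
      background = rep(1 / 20, 20), motifColumns = integer(0),
      referenceLength = as.integer(L), mu = NA_real_, lambda = NA_real_)
}

# closed-form Welch statistic and Student-t tail
welchOracle <- function(x, y, alternative = "greater") {
  m1 <- mean(x); m2 <- mean(y)
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  p <- if (alternative == "greater") pt(t, df, lower.tail = FALSE)
  else 2 * pt(abs(t), df, lower.tail = FALSE)
  list(statistic = t, df = df, pValue = p)
}

# textbook 2x2 chi-square on the implied contingency table, with and
# without the Yates continuity correction
chisqOracle <- function(x1, n1, x2, n2, correct = FALSE) {
  O <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  if (correct) {
    adj <- pmin(abs(O - E), 0.5)
    stat <- sum((abs(O - E) - adj)^2 / E)
  } else {
    stat <- sum((O - E)^2 / E)
  }
  list(statistic = stat, pValue = pchisq(stat, 1, lower.tail = FALSE))
}

rgumbel <- function(n, mu, lambda) mu - log(-log(runif(n))) / lambda

aaAlphabet <- function() c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                           "L", "M", "N", "P", "Q", "R", "S", "T", "V",
                           "W", "Y")

randomAASeq <- function(n) paste(sample(aaAlphabet(), n, TRUE),
                                 collapse = "")
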