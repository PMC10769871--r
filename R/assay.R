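#' @include config.R
NULL

#' Fluorescence ratio of a sample to the abiotic control
#'
#' Ratio of the mean replicate fluorescence of a strain to the mean of the
#' abiotic media control (the quantity plotted as bars in the screening
#' assay). `center = "median"` is available for robustness checks.
#'
#' @param sampleValues,controlValues positive replicate fluorescence values.
#' @param center "mean" (default) or "median".
#' @return a single dimensionless ratio.
#' @examples
#' fluorescenceRatio(c(100, 110, 90), c(10, 10, 10))
#' @export
fluorescenceRatio <- function(sampleValues, controlValues,
                              center = c("mean", "median")) {
  center <- match.arg(center)
  if (!length(sampleValues) || !length(controlValues))
    stop("replicate vectors must be non-empty")
  if (any(!is.finite(sampleValues)) || any(!is.finite(controlValues)) ||
      any(sampleValues < 0) || any(controlValues < 0))
    stop("fluorescence values must be finite and non-negative")
  f <- if (center == "mean") mean else median
  cm <- f(controlValues)
  if (cm <= 0) stop("control center must be > 0")
  f(sampleValues) / cm
}

#' Call a strain a bilirubin reducer from its fluorescence ratio
#'
#' A strain is positive for bilirubin reduction when its fluorescence ratio
#' strictly exceeds the threshold (default 5); a ratio of exactly 5 is a
#' non-reducer.
#'
#' @param ratio non-negative fluorescence ratio.
#' @param threshold positive ratio threshold.
#' @return logical.
#' @examples
#' callReducer(5)      # FALSE: the boundary is strict
#' callReducer(5.0001) # TRUE
#' @export
callReducer <- function(ratio, threshold = 5) {
  if (any(ratio < 0)) stop("'ratio' must be >= 0")
  ratio > threshold
}

#' Two-sample t-test on log2-transformed values
#'
#' Welch's (default) or pooled two-sample t-test applied to log2-transformed
#' fluorescence values, with a one-sided `greater` alternative (is group A's
#' mean log2 fluorescence greater than group B's?) or a two-sided one.
#'
#' @param groupA,groupB positive values, at least 2 per group.
#' @param alternative "greater" (one-sided, default) or "two.sided".
#' @param varEqual pool variances? Welch (FALSE) is the default.
#' @return list with `statistic`, `pValue` and `df`.
#' @examples
#' log2TTest(c(8, 8.2, 7.9, 8.1), c(2, 2.1, 1.9, 2.05))$pValue
#' @export
log2TTest <- function(groupA, groupB,
                      alternative = c("greater", "two.sided"),
                      varEqual = FALSE) {
  alternative <- match.arg(alternative)
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs >= 2 values")
  if (any(groupA <= 0) || any(groupB <= 0))
    stop("values must be strictly positive to log2-transform")
  la <- log2(groupA); lb <- log2(groupB)
  # degenerate case t.test refuses: both groups (near-)constant
  tiny <- max(abs(c(la, lb)), 1) * .Machine$double.eps
  if (sd(la) < tiny && sd(lb) < tiny) {
    d <- mean(la) - mean(lb)
    t <- if (abs(d) < tiny) 0 else sign(d) * Inf
    p <- if (t == 0) { if (alternative == "greater") 0.5 else 1 }
    else if (alternative == "greater") { if (t > 0) 0 else 1 } else 0
    return(list(statistic = t, pValue = p,
                df = length(la) + length(lb) - 2))
  }
  tt <- t.test(la, lb, alternative = alternative, var.equal = varEqual)
  list(statistic = unname(tt$statistic), pValue = tt$p.value,
       df = unname(tt$parameter))
}

#' Phenotype calls for a fluorescence assay table
#'
#' For every strain: the fluorescence ratio to the abiotic control, the
#' reducer call at the (strict) ratio threshold, and a one-sided t-test on
#' log2-transformed raw fluorescence against the control replicates.
#'
#' @param x a [FluorescenceFixture-class], or a data.frame with columns
#'   `strain`, `value` and control rows flagged by `strain == "control"`.
#' @param config a [BilrConfig-class]; supplies the ratio threshold.
#' @param threshold overrides the config threshold when given.
#' @return a data.frame with columns strain, ratio, isReducer, pValue.
#' @examples
#' fl <- generateFluorescence(c("a", "b"), foldChange = 20, cv = 0.05,
#'                            nReps = 3, seed = 1, reducers = "a")
#' assayCalls(fl)
#' @export
assayCalls <- function(x, config = bilrConfig(),
                       threshold = config@fluorescenceThreshold) {
  if (is(x, "FluorescenceFixture")) {
    meas <- measurements(x)
    ctrl <- controlValues(x)
  } else {
    x <- as.data.frame(x)
    if (!all(c("strain", "value") %in% colnames(x)))
      stop("table must have columns 'strain' and 'value'")
    ctrl <- x$value[x$strain == "control"]
    if (!length(ctrl)) stop("no control rows (strain == \"control\")")
    keep <- x$strain != "control"
    meas <- split(x$value[keep], x$strain[keep])
  }
  out <- data.frame(
    strain = names(meas),
    ratio = vapply(meas, fluorescenceRatio, numeric(1),
                   controlValues = ctrl),
    stringsAsFactors = FALSE)
  out$isReducer <- callReducer(out$ratio, threshold)
  out$pValue <- vapply(meas, function(v)
    log2TTest(v, ctrl, alternative = "greater")$pValue, numeric(1))
  rownames(out) <- NULL
  out
}
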