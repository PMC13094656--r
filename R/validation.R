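# Method-agreement machinery: paired regression and Bland-Altman analysis.

#' Paired simple linear regression with Pearson correlation
#'
#' Ordinary least squares of \code{y} on \code{x} plus the Pearson correlation
#' of the pairs, as used to compare automated counts against manual counts.
#'
#' @param x,y paired numeric vectors (e.g. manual and automated counts).
#' @return A [RegressionResult-class].
#' @examples
#' pairedRegression(1:10, 2 * (1:10) + 1)
#' @export
pairedRegression <- function(x, y) {
  if (length(x) != length(y))
    sgStop("sgLengthMismatch", "x and y differ in length")
  if (length(x) < 3) sgStop("sgTooFewPairs", "need at least 3 pairs")
  if (sd(x) == 0) sgStop("sgZeroVariance", "x is constant")
  fit <- lm(y ~ x)
  r <- if (sd(y) == 0) 0 else cor(x, y)
  new("RegressionResult", slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]), pearsonR = r, rSquared = r^2,
      n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Differences are defined automated minus manual (\code{a - b}), so a
#' negative bias means the automated method underestimates. The limits of
#' agreement are bias +/- \code{multiplier} x sample SD of the differences
#' (n - 1 denominator); pairs with differences outside the limits are
#' reported as outliers.
#'
#' The default multiplier 1.96 corresponds to conventional 95% limits; pass
#' \code{multiplier = qnorm(0.98)} (about 2.054) for 96% limits.
#'
#' @param a numeric vector, method A (automated).
#' @param b numeric vector, method B (manual), same length.
#' @param multiplier limits-of-agreement multiplier (default 1.96).
#' @return An [AgreementResult-class].
#' @examples
#' blandAltman(c(8, 10, 12), c(10, 10, 10))
#' @export
blandAltman <- function(a, b, multiplier = 1.96) {
  if (length(a) != length(b))
    sgStop("sgLengthMismatch", "a and b differ in length")
  if (length(a) < 2) sgStop("sgTooFewPairs", "need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  lo <- bias - multiplier * s
  hi <- bias + multiplier * s
  out <- which(d < lo | d > hi)
  new("AgreementResult", nPairs = length(a), bias = bias, sdDiff = s,
      loaLow = lo, loaHigh = hi, multiplier = multiplier,
      differences = d, means = (a + b) / 2, outlierIds = as.integer(out))
}

#' Stratified Bland-Altman agreement
#'
#' Pairs are binned by the mean of the two measurements against sorted
#' stratum edges using half-open bins \code{[lo, hi)} (a mean exactly on an
#' edge goes to the upper stratum), and [blandAltman()] is applied per
#' stratum. Strata with fewer than 2 pairs are reported as \code{NULL}.
#'
#' @param a,b paired numeric vectors.
#' @param strataEdges sorted numeric thresholds, e.g. \code{c(5000, 10000)}.
#' @param multiplier limits-of-agreement multiplier.
#' @return Named list of [AgreementResult-class] (or \code{NULL}) per stratum.
#' @export
stratifiedAgreement <- function(a, b, strataEdges, multiplier = 1.96) {
  if (is.unsorted(strataEdges))
    sgStop("sgBadConfig", "strataEdges must be sorted")
  mids <- (a + b) / 2
  stratum <- findInterval(mids, strataEdges) + 1L  # [lo, hi) bins
  edgesTxt <- c("-Inf", format(strataEdges, trim = TRUE), "Inf")
  nm <- paste0("[", edgesTxt[-length(edgesTxt)], ",", edgesTxt[-1], ")")
  out <- setNames(vector("list", length(strataEdges) + 1L), nm)
  for (s in seq_along(out)) {
    sel <- stratum == s
    if (sum(sel) >= 2)
      out[[s]] <- blandAltman(a[sel], b[sel], multiplier)
  }
  out
}
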