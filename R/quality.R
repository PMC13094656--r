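# Image-level staining-quality metrics, quality classification, and
# segmentation-deviation QC.

#' Image staining-quality metrics
#'
#' Whole-image metrics for one channel: the focus score is the normalized
#' variance \eqn{\mathrm{var}(I)/\mathrm{mean}(I)^2} (population variance; it
#' decreases monotonically under defocus blur), plus mean/SD/median-absolute-
#' deviation intensity, the percentage of pixels at the channel maximum, and a
#' 256-bin histogram.
#'
#' @param image [MultichannelImage-class].
#' @param role channel role to assess.
#' @return List with \code{image_id}, \code{role}, \code{focus_score}
#'   (\code{NA} and flagged for an all-zero channel), \code{mean_intensity},
#'   \code{std_intensity}, \code{mad_intensity}, \code{percent_maximal},
#'   \code{histogram} (counts summing to the pixel number).
#' @export
qualityMetrics <- function(image, role = "membrane") {
  g <- channel(image, role)
  v <- as.numeric(g)
  mu <- mean(v)
  varP <- mean((v - mu)^2)
  hist <- tabulate(pmin(pmax(floor(v * 256), 0), 255) + 1L, nbins = 256)
  list(image_id = imageId(image), role = role,
       focus_score = if (mu > 0) varP / mu^2 else NA_real_,
       focus_undefined = mu == 0,
       mean_intensity = mu,
       std_intensity = sqrt(varP),
       mad_intensity = median(abs(v - median(v))),
       percent_maximal = 100 * mean(v == max(v)),
       histogram = hist)
}

#' Segmentation deviation between automated and manual counts
#'
#' Absolute difference in cell counts between automated segmentation and
#' manual annotation, plus the percentage deviation relative to the manual
#' count (undefined and flagged when the manual count is zero).
#'
#' @param auto automated cell count.
#' @param manual manual cell count.
#' @param imageId optional identifier carried into the record.
#' @return List with \code{auto_count}, \code{manual_count},
#'   \code{abs_deviation}, \code{pct_deviation}, \code{pct_undefined}.
#' @export
segmentationDeviation <- function(auto, manual, imageId = NA_character_) {
  if (auto < 0 || manual < 0)
    sgStop("sgNegativeCounts", "counts must be non-negative")
  absd <- abs(auto - manual)
  list(image_id = imageId, auto_count = auto, manual_count = manual,
       abs_deviation = absd,
       pct_deviation = if (manual > 0) 100 * absd / manual else NA_real_,
       pct_undefined = manual == 0)
}

#' Correlate a quality metric with segmentation deviation
#'
#' Pearson correlation with \eqn{R^2 = r^2} and a two-sided p-value from the
#' t-distribution with n - 2 degrees of freedom.
#'
#' @param metrics numeric vector of per-image quality metric values.
#' @param deviations numeric vector of per-image segmentation deviations.
#' @return List with \code{r}, \code{r_squared}, \code{p_value}, \code{n}.
#' @export
correlateMetricWithDeviation <- function(metrics, deviations) {
  if (length(metrics) != length(deviations))
    sgStop("sgLengthMismatch", "metrics and deviations differ in length")
  n <- length(metrics)
  if (n < 3) sgStop("sgTooFewPairs", "need at least 3 pairs")
  if (sd(metrics) == 0 || sd(deviations) == 0)
    sgStop("sgZeroVariance", "zero-variance input has no correlation")
  ct <- cor.test(metrics, deviations, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value, n = n)
}

#' Classify staining quality
#'
#' Threshold rule mirroring histogram-based visual triage: an image is
#' \code{"high"} quality iff its focus score and intensity SD both reach
#' their thresholds, otherwise \code{"low"}. Thresholds are calibration
#' parameters to be set per staining batch.
#'
#' @param record list from [qualityMetrics()].
#' @param thresholdFocus minimum focus score for high quality.
#' @param thresholdStd minimum intensity SD for high quality.
#' @return \code{"high"} or \code{"low"}.
#' @export
classifyStainingQuality <- function(record, thresholdFocus, thresholdStd) {
  if (isTRUE(record$focus_undefined)) return("low")
  if (record$focus_score >= thresholdFocus &&
      record$std_intensity >= thresholdStd) "high" else "low"
}
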