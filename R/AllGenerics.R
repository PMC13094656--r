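# Generics, accessors and show methods.

#' Extract a channel from a MultichannelImage
#'
#' @param x a [MultichannelImage-class].
#' @param role one of \code{"nuclear"}, \code{"membrane"}, \code{"marker"}.
#' @return The channel's intensity matrix.
#' @export
setGeneric("channel", function(x, role) standardGeneric("channel"))

#' @rdname channel
#' @export
setMethod("channel", "MultichannelImage", function(x, role) {
  if (!role %in% names(x@channels))
    sgStop("sgChannelMissing", sprintf("channel role '%s' not present", role))
  x@channels[[role]]
})

#' Channel roles present in an image
#' @param x a [MultichannelImage-class].
#' @return Character vector of roles.
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname channelRoles
#' @export
setMethod("channelRoles", "MultichannelImage", function(x) names(x@channels))

#' Image identifier
#' @param x a [MultichannelImage-class].
#' @return Character identifier.
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' @rdname imageId
#' @export
setMethod("imageId", "MultichannelImage", function(x) x@imageId)

#' Pixel size in micrometres per pixel
#' @param x a [MultichannelImage-class].
#' @return Numeric scalar (possibly \code{NA}).
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "MultichannelImage", function(x) x@pixelSize)

#' @export
#' @describeIn MultichannelImage image geometry as \code{c(height, width)}.
setMethod("dim", "MultichannelImage", function(x) dim(x@channels[[1]]))

setMethod("show", "MultichannelImage", function(object) {
  d <- dim(object)
  cat(sprintf("MultichannelImage '%s': %d x %d px, channels: %s\n",
              object@imageId, d[1], d[2],
              paste(names(object@channels), collapse = ", ")))
  if (!is.na(object@pixelSize))
    cat(sprintf("  pixel size: %.4g um/px\n", object@pixelSize))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  nucleus diameter band: [%g, %g] px\n",
              object@nucleusDiameterMin, object@nucleusDiameterMax))
  cat(sprintf("  spot area band: [%g, %g] px\n",
              object@spotAreaMin, object@spotAreaMax))
  cat(sprintf("  smoothing sigma: %g px; expansion: %g px\n",
              object@smoothingSigma, object@expansionDistance))
  cat(sprintf("  radial bins: %d; positive at >= %d spots\n",
              object@nRadialBins, object@minSpotsPositive))
  cat(sprintf("  oversize factor: %g; epithelial overlap max: %g\n",
              object@areaFilterFactor, object@epcamOverlapMax))
  cat(sprintf("  threshold: %s%s\n", object@thresholdMethod,
              if (object@thresholdMethod == "manual")
                sprintf(" (%.4g)", object@manualThreshold) else ""))
})

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf(
    "Bland-Altman agreement over %d pairs\n  bias %.4g, SD %.4g, LoA [%.4g, %.4g] (x%.3g)\n  outliers: %d\n",
    object@nPairs, object@bias, object@sdDiff, object@loaLow,
    object@loaHigh, object@multiplier, length(object@outlierIds)))
})

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf(
    "Paired regression (n = %d): slope %.4g, intercept %.4g, r %.4g, R^2 %.4g\n",
    object@n, object@slope, object@intercept, object@pearsonR,
    object@rSquared))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %dx%d px, %d crypt(s), %d epithelial nuclei/crypt, lamina density %.3g/10^4 px^2\n  group '%s', seed %d, noise %.3g, blur %.3g\n",
    object@size, object@size, object@nCrypts,
    object@epithelialNucleiPerCrypt, object@laminaDensity, object@group,
    object@seed, object@noiseSigma, object@blurSigma))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf(
    "SceneTruth (%s): %d nuclei (%d epithelial, %d lamina), %d spots\n",
    object@group, nrow(object@cellInfo),
    sum(object@cellInfo$compartment == "epithelial"),
    sum(object@cellInfo$compartment == "lamina"),
    length(labelIds(object@spots))))
})

setMethod("show", "RunManifest", function(object) {
  cat(sprintf("RunManifest: pipeline '%s' on image '%s' (v%s, seed %d)\n",
              object@pipeline, object@imageId, object@version, object@seed))
  for (nm in names(object@stageCounts))
    cat(sprintf("  %-28s %d\n", nm, object@stageCounts[[nm]]))
})
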