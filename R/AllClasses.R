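# S4 classes for the package's central data objects.

#' Multichannel fluorescence image
#'
#' Container for one 2-D field of view with role-keyed channels. Channels are
#' stored as base matrices of intensities normalized to \code{[0, 1]}; the
#' recognised roles are \code{"nuclear"} (DNA stain such as DAPI),
#' \code{"membrane"} (epithelial membrane marker such as EpCAM) and
#' \code{"marker"} (the target protein, e.g. the stress-granule nucleator
#' G3BP1). All channels share one geometry.
#'
#' @slot imageId character identifier of the field of view.
#' @slot channels named list of numeric matrices, names among
#'   \code{nuclear}, \code{membrane}, \code{marker}.
#' @slot pixelSize micrometres per pixel, or \code{NA} when unknown.
#'
#' @seealso [loadImage()], [channel()], [generateScene()]
#' @export
setClass("MultichannelImage",
  representation(imageId = "character", channels = "list",
                 pixelSize = "numeric"),
  prototype(imageId = "image", channels = list(), pixelSize = NA_real_))

setValidity("MultichannelImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0) return("at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named by role")
  bad <- setdiff(names(ch), c("nuclear", "membrane", "marker"))
  if (length(bad)) return(paste("unknown channel role:", bad[1]))
  d <- dim(ch[[1]])
  for (nm in names(ch)) {
    m <- ch[[nm]]
    if (!is.matrix(m) || !is.numeric(m))
      return(sprintf("channel '%s' is not a numeric matrix", nm))
    if (!identical(dim(m), d))
      return("channels have mismatched geometry")
    if (any(dim(m) < 1)) return("channel geometry must be at least 1x1")
    if (anyNA(m) || min(m) < 0 || max(m) > 1)
      return(sprintf("channel '%s' has intensities outside [0, 1]", nm))
  }
  TRUE
})

#' Construct a MultichannelImage
#'
#' @param channels named list of numeric matrices in \code{[0, 1]}; names are
#'   channel roles (\code{nuclear}, \code{membrane}, \code{marker}).
#' @param imageId identifier string.
#' @param pixelSize optional micrometres per pixel.
#' @return A [MultichannelImage-class] object.
#' @examples
#' img <- MultichannelImage(list(nuclear = matrix(runif(64), 8)))
#' dim(img)
#' @export
MultichannelImage <- function(channels, imageId = "image",
                              pixelSize = NA_real_) {
  new("MultichannelImage", imageId = imageId,
      channels = lapply(channels, function(m) {
        m <- asMat(m); storage.mode(m) <- "double"; m
      }),
      pixelSize = as.numeric(pixelSize))
}

#' Pipeline configuration
#'
#' Tunable parameters shared by the epithelial (ECP) and lamina propria (PCP)
#' workflows. All sizes are in pixels. Defaults follow the printed rules where
#' the source workflow states them (3 radial bins; positivity at >= 2 spots;
#' oversize removal at 3x the mean area) and documented conventions elsewhere.
#'
#' @slot nucleusDiameterMin,nucleusDiameterMax admissible equivalent-diameter
#'   band for nuclei (px).
#' @slot spotAreaMin,spotAreaMax admissible spot area band (px).
#' @slot smoothingSigma Gaussian smoothing sigma before thresholding (px).
#' @slot expansionDistance radial cell expansion around lamina nuclei (px).
#' @slot nRadialBins number of radial cytoplasm bins.
#' @slot minSpotsPositive minimum spot count for a positive cell.
#' @slot areaFilterFactor oversize removal threshold as a multiple of the
#'   mean cell area.
#' @slot epcamOverlapMax maximum tolerated fraction of a lamina cell inside
#'   the epithelial region.
#' @slot thresholdMethod \code{"otsu"} or \code{"manual"}.
#' @slot manualThreshold threshold in \code{[0, 1]} when manual.
#' @slot rngSeed integer seed recorded into run manifests.
#' @export
setClass("PipelineConfig",
  representation(
    nucleusDiameterMin = "numeric", nucleusDiameterMax = "numeric",
    spotAreaMin = "numeric", spotAreaMax = "numeric",
    smoothingSigma = "numeric", expansionDistance = "numeric",
    nRadialBins = "integer", minSpotsPositive = "integer",
    areaFilterFactor = "numeric", epcamOverlapMax = "numeric",
    thresholdMethod = "character", manualThreshold = "numeric",
    rngSeed = "integer"),
  prototype(
    nucleusDiameterMin = 8, nucleusDiameterMax = 40,
    spotAreaMin = 2, spotAreaMax = 200,
    smoothingSigma = 1, expansionDistance = 5,
    nRadialBins = 3L, minSpotsPositive = 2L,
    areaFilterFactor = 3, epcamOverlapMax = 0.5,
    thresholdMethod = "otsu", manualThreshold = NA_real_, rngSeed = 1L))

setValidity("PipelineConfig", function(object) {
  if (object@nucleusDiameterMin <= 0 || object@spotAreaMin <= 0 ||
      object@smoothingSigma < 0 || object@expansionDistance < 0)
    return("sizes must be positive (sigma/expansion non-negative)")
  if (object@nucleusDiameterMin > object@nucleusDiameterMax)
    return("nucleusDiameterMin must not exceed nucleusDiameterMax")
  if (object@spotAreaMin > object@spotAreaMax)
    return("spotAreaMin must not exceed spotAreaMax")
  if (object@nRadialBins < 1L) return("nRadialBins must be >= 1")
  if (object@minSpotsPositive < 0L) return("minSpotsPositive must be >= 0")
  if (object@areaFilterFactor <= 0) return("areaFilterFactor must be > 0")
  if (object@epcamOverlapMax < 0 || object@epcamOverlapMax > 1)
    return("epcamOverlapMax must be a fraction in [0, 1]")
  if (!object@thresholdMethod %in% c("otsu", "manual"))
    return("thresholdMethod must be 'otsu' or 'manual'")
  if (object@thresholdMethod == "manual" &&
      (is.na(object@manualThreshold) || object@manualThreshold < 0 ||
       object@manualThreshold > 1))
    return("manualThreshold must be in [0, 1] when thresholdMethod='manual'")
  TRUE
})

#' Construct a PipelineConfig
#'
#' @param ... named values overriding the defaults documented in
#'   [PipelineConfig-class].
#' @return A validated [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig(expansionDistance = 8)
#' cfg@minSpotsPositive
#' @export
pipelineConfig <- function(...) {
  args <- list(...)
  for (nm in c("nRadialBins", "minSpotsPositive", "rngSeed"))
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("PipelineConfig"), args))
}

#' Bland-Altman method-agreement result
#'
#' @slot nPairs number of paired measurements.
#' @slot bias mean difference (method A minus method B).
#' @slot sdDiff sample standard deviation of the differences.
#' @slot loaLow,loaHigh limits of agreement, bias -/+ multiplier x sdDiff.
#' @slot multiplier limits-of-agreement multiplier (1.96 for 95%).
#' @slot differences,means per-pair differences and means.
#' @slot outlierIds indices of pairs outside the limits of agreement.
#' @export
setClass("AgreementResult",
  representation(nPairs = "integer", bias = "numeric", sdDiff = "numeric",
                 loaLow = "numeric", loaHigh = "numeric",
                 multiplier = "numeric", differences = "numeric",
                 means = "numeric", outlierIds = "integer"))

setValidity("AgreementResult", function(object) {
  if (!is.na(object@bias) && !is.na(object@loaLow) &&
      (object@loaLow > object@bias + 1e-12 ||
       object@loaHigh < object@bias - 1e-12))
    return("limits of agreement must bracket the bias")
  TRUE
})

#' Paired regression result
#'
#' @slot slope,intercept ordinary least squares fit of y on x.
#' @slot pearsonR Pearson correlation of the pairs.
#' @slot rSquared squared correlation.
#' @slot n number of pairs.
#' @export
setClass("RegressionResult",
  representation(slope = "numeric", intercept = "numeric",
                 pearsonR = "numeric", rSquared = "numeric", n = "integer"))

#' Synthetic scene specification
#'
#' Parameters of the mucosa-like scene generator: ring-shaped crypt epithelium
#' with a membrane-marker band, scattered lamina propria nuclei, per-cell
#' Poisson spot counts, and acquisition degradation (noise/blur). See
#' [sceneSpec()] for defaults and units.
#'
#' @slot size image side length (px, square images).
#' @slot nCrypts number of crypt cross-sections.
#' @slot cryptInnerRadius,cryptOuterRadius epithelial annulus radii (px).
#' @slot epithelialNucleiPerCrypt nuclei rendered on each crypt ring.
#' @slot laminaDensity lamina nuclei per 10^4 px^2 of lamina area.
#' @slot nucleusRadiusMean,nucleusRadiusSd nucleus radius distribution (px).
#' @slot irregularity amplitude of the radial Fourier perturbation of the
#'   nuclear outline (dimensionless).
#' @slot spotRateNuclear,spotRateCytoplasmic Poisson spot rates per cell and
#'   compartment.
#' @slot spotRadius spot disc radius (px).
#' @slot nuclearIntensity,membraneIntensity,spotIntensity,markerBaseline
#'   rendered channel intensities (AU in \code{[0, 1]}).
#' @slot noiseSigma additive Gaussian noise SD (AU).
#' @slot blurSigma Gaussian blur sigma applied to all channels (px).
#' @slot group \code{"control"} or \code{"remission"} (remission-like scenes
#'   scale spot rate, spot size, marker intensity, nucleus size and
#'   irregularity).
#' @slot seed integer RNG seed; scenes are reproducible bit-exactly.
#' @export
setClass("SceneSpec",
  representation(
    size = "integer", nCrypts = "integer",
    cryptInnerRadius = "numeric", cryptOuterRadius = "numeric",
    epithelialNucleiPerCrypt = "integer", laminaDensity = "numeric",
    nucleusRadiusMean = "numeric", nucleusRadiusSd = "numeric",
    irregularity = "numeric",
    spotRateNuclear = "numeric", spotRateCytoplasmic = "numeric",
    spotRadius = "numeric",
    nuclearIntensity = "numeric", membraneIntensity = "numeric",
    spotIntensity = "numeric", markerBaseline = "numeric",
    noiseSigma = "numeric", blurSigma = "numeric",
    group = "character", seed = "integer"))

setValidity("SceneSpec", function(object) {
  if (object@size < 32) return("size must be >= 32 px")
  if (object@cryptInnerRadius <= 0 ||
      object@cryptOuterRadius <= object@cryptInnerRadius)
    return("crypt radii must satisfy 0 < inner < outer")
  if (object@nucleusRadiusMean <= 0) return("nucleus radius must be positive")
  if (object@spotRateNuclear < 0 || object@spotRateCytoplasmic < 0)
    return("spot rates must be >= 0")
  if (object@spotRadius <= 0) return("spot radius must be positive")
  if (object@noiseSigma < 0 || object@blurSigma < 0)
    return("noise and blur sigmas must be >= 0")
  if (!object@group %in% c("control", "remission"))
    return("group must be 'control' or 'remission'")
  TRUE
})

#' Synthetic scene ground truth
#'
#' @slot nuclei,cells,spots integer label maps rendered by the generator
#'   (recorded before noise/blur degradation).
#' @slot cellInfo per-cell data.frame: \code{cell_id}, \code{compartment}
#'   (\code{epithelial}/\code{lamina}), true spot counts split by compartment,
#'   nucleus area and centroid.
#' @slot group scene group label.
#' @export
setClass("SceneTruth",
  representation(nuclei = "matrix", cells = "matrix", spots = "matrix",
                 cellInfo = "data.frame", group = "character"))

#' Pipeline run manifest
#'
#' Audit record of one ECP/PCP run: which pipeline, per-stage object counts
#' (masking and filtering can only decrease them), the full configuration
#' snapshot, software version and seed. Together with the input image a
#' manifest fully determines a rerun.
#'
#' @slot pipeline \code{"ecp"} or \code{"pcp"}.
#' @slot imageId input image identifier.
#' @slot stageCounts named integer vector of per-stage object counts.
#' @slot config [PipelineConfig-class] snapshot.
#' @slot version package version string.
#' @slot seed integer seed recorded from the configuration.
#' @slot timestamp run wall-clock time (informational only; not part of the
#'   deterministic output surface).
#' @export
setClass("RunManifest",
  representation(pipeline = "character", imageId = "character",
                 stageCounts = "integer", config = "PipelineConfig",
                 version = "character", seed = "integer",
                 timestamp = "character"))
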