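# Seeded generator of mucosa-like multichannel scenes with full ground truth.
#
# The rendered geometry emulates a colonic mucosa cross-section: each crypt is
# an annular epithelial band (membrane-marker positive) carrying a ring of
# epithelial nuclei; lamina propria nuclei are scattered outside the crypts
# with a minimum separation; marker spots are Poisson-distributed per cell and
# compartment; Gaussian noise and blur model acquisition. Ground truth is
# recorded before degradation.

# Group-level effect multipliers applied to remission-like scenes: spot rate,
# spot radius, marker intensity scale, nucleus radius and outline
# irregularity all increase, mirroring the directional differences the
# pipelines are designed to resolve.
remissionMultipliers <- function(group) {
  if (group == "remission")
    list(rate = 1.6, spotR = 1.25, marker = 1.5, nucR = 1.15, irr = 2.0)
  else
    list(rate = 1, spotR = 1, marker = 1, nucR = 1, irr = 1)
}

#' Construct a synthetic scene specification
#'
#' Defaults describe one 256x256 px field with a single crypt cross-section
#' (annulus radii 34/66 px) carrying 14 epithelial nuclei, lamina nuclei at
#' 6 per 10^4 px^2, near-circular nuclei of radius ~6 px, cytoplasmic spot
#' rate 5 and nuclear rate 0.6 per cell, spot radius 1.6 px, and mild
#' acquisition degradation (noise SD 0.02, blur sigma 0.5). Zero-noise
#' variants (\code{noiseSigma = 0, blurSigma = 0}) are the reference
#' condition for segmentation-accuracy checks.
#'
#' @param ... named overrides of the slots in [SceneSpec-class].
#' @return A validated [SceneSpec-class].
#' @examples
#' spec <- sceneSpec(seed = 7, group = "remission")
#' @export
sceneSpec <- function(...) {
  args <- list(size = 256L, nCrypts = 1L, cryptInnerRadius = 34,
               cryptOuterRadius = 66, epithelialNucleiPerCrypt = 14L,
               laminaDensity = 6, nucleusRadiusMean = 6,
               nucleusRadiusSd = 0.6, irregularity = 0.06,
               spotRateNuclear = 0.6, spotRateCytoplasmic = 5,
               spotRadius = 1.6, nuclearIntensity = 0.8,
               membraneIntensity = 0.75, spotIntensity = 0.9,
               markerBaseline = 0.1, noiseSigma = 0.02, blurSigma = 0.5,
               group = "control", seed = 1L)
  override <- list(...)
  args[names(override)] <- override
  for (nm in c("size", "nCrypts", "epithelialNucleiPerCrypt", "seed"))
    args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("SceneSpec"), args))
}

# Render one irregular nucleus disc into a label map; returns modified map.
# Outline: r(theta) = r0 * (1 + irr*(0.6 cos(2 theta + p2) + 0.4 cos(3 theta
# + p3))), a low-order radial Fourier perturbation of a circle.
renderNucleus <- function(lab, cr, cc, r0, irr, label) {
  h <- nrow(lab); w <- ncol(lab)
  rmax <- r0 * (1 + abs(irr))
  p2 <- runif(1, 0, 2 * pi); p3 <- runif(1, 0, 2 * pi)
  r0i <- max(1L, floor(cr - rmax)); r1i <- min(h, ceiling(cr + rmax))
  c0i <- max(1L, floor(cc - rmax)); c1i <- min(w, ceiling(cc + rmax))
  rows <- r0i:r1i; cols <- c0i:c1i
  dr <- outer(rows - cr, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cc)
  dist <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)
  redge <- r0 * (1 + irr * (0.6 * cos(2 * theta + p2) +
                            0.4 * cos(3 * theta + p3)))
  inside <- dist <= redge
  sub <- lab[rows, cols, drop = FALSE]
  sub[inside & sub == 0L] <- label
  lab[rows, cols] <- sub
  lab
}

# Nearest-seed partition of `domain` pixels among nuclei labels (Euclidean,
# ties to the lower label), used for ground-truth epithelial cells.
nearestNucleusPartition <- function(nuclei, domain, maxDist = Inf) {
  ids <- labelIds(nuclei)
  h <- nrow(nuclei); w <- ncol(nuclei)
  out <- matrix(0L, h, w)
  if (length(ids) == 0) return(out)
  bestD <- matrix(Inf, h, w)
  for (L in ids) {
    dL <- asMat(EBImage::distmap(nuclei != L))
    upd <- dL < bestD
    bestD[upd] <- dL[upd]
    out[upd] <- L
  }
  out[!domain | bestD > maxDist] <- 0L
  out[nuclei > 0] <- nuclei[nuclei > 0]
  out
}

#' Generate a synthetic mucosa scene with ground truth
#'
#' Deterministic for a fixed spec: the same seed gives bit-identical images
#' and truth. All randomness flows from one locally seeded generator; global
#' RNG state is untouched.
#'
#' @param spec a [SceneSpec-class].
#' @param cellExpansion lamina ground-truth cell radius beyond the nucleus
#'   (px); matches the default pipeline expansion distance.
#' @return List with \code{image} ([MultichannelImage-class]) and
#'   \code{truth} ([SceneTruth-class]).
#' @examples
#' sc <- generateScene(sceneSpec(size = 128, laminaDensity = 3, seed = 2))
#' sc$truth
#' @export
generateScene <- function(spec, cellExpansion = 5) {
  validObject(spec)
  withLocalSeed(spec@seed, {
    mult <- remissionMultipliers(spec@group)
    size <- spec@size
    nucR <- spec@nucleusRadiusMean * mult$nucR
    nucSd <- spec@nucleusRadiusSd
    irr <- spec@irregularity * mult$irr
    spotRad <- spec@spotRadius * mult$spotR
    baseline <- min(0.5, spec@markerBaseline * mult$marker)
    spotInt <- min(1, spec@spotIntensity * min(mult$marker, 1.1))
    rateN <- spec@spotRateNuclear * mult$rate
    rateC <- spec@spotRateCytoplasmic * mult$rate

    # crypt centers along the horizontal midline
    n <- spec@nCrypts
    cx <- size * seq_len(n) / (n + 1)
    cy <- rep(size / 2, n)
    if (n > 1 && min(diff(cx)) < 2 * spec@cryptOuterRadius + 8)
      sgStop("sgPacking", "crypts do not fit the image without overlap")
    if (spec@cryptOuterRadius + 2 > size / 2 && n == 1)
      sgStop("sgPacking", "crypt larger than the image")

    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    distCrypt <- matrix(Inf, size, size)
    for (k in seq_len(n)) {
      d <- sqrt((rows - cy[k])^2 + (cols - cx[k])^2)
      distCrypt <- pmin(distCrypt, d)
    }
    bandMask <- distCrypt >= spec@cryptInnerRadius &
      distCrypt <= spec@cryptOuterRadius
    filledMask <- distCrypt <= spec@cryptOuterRadius

    nucLab <- matrix(0L, size, size)
    compartment <- character(0)
    label <- 0L

    # epithelial nuclei on each crypt ring, kept inside the band
    midR <- (spec@cryptInnerRadius + spec@cryptOuterRadius) / 2
    halfBand <- (spec@cryptOuterRadius - spec@cryptInnerRadius) / 2
    kE <- spec@epithelialNucleiPerCrypt
    for (k in seq_len(n)) {
      ang <- 2 * pi * (seq_len(kE) - 1) / kE +
        runif(kE, -0.25, 0.25) * 2 * pi / kE
      for (j in seq_len(kE)) {
        r0 <- min(max(rnorm(1, nucR, nucSd), 0.7 * nucR), 1.3 * nucR)
        rmax <- r0 * (1 + irr)
        slack <- max(0, halfBand - rmax - 1)
        rad <- midR + runif(1, -slack, slack)
        cr <- cy[k] + rad * sin(ang[j])
        cc <- cx[k] + rad * cos(ang[j])
        label <- label + 1L
        nucLab <- renderNucleus(nucLab, cr, cc, r0, irr, label)
        compartment <- c(compartment, "epithelial")
      }
    }
    nEpi <- label

    # lamina nuclei: dart throwing outside the crypts with minimum separation
    margin <- ceiling(nucR * (1 + irr)) + 2
    # lamina propria cells sit right against the basement membrane: centers
    # start 2 px outside the band, so membrane staining quality genuinely
    # conditions how well masking separates the compartments
    laminaOK <- distCrypt > spec@cryptOuterRadius + 2 &
      rows > margin & rows <= size - margin &
      cols > margin & cols <= size - margin
    laminaArea <- sum(distCrypt > spec@cryptOuterRadius + 2)
    nLam <- round(spec@laminaDensity * laminaArea / 1e4)
    minSep <- 2.8 * nucR
    centers <- matrix(numeric(0), 0, 2)
    candidates <- which(laminaOK)
    if (nLam > 0) {
      if (length(candidates) < nLam * 4)
        sgStop("sgPacking", "too many lamina nuclei for the available area")
      tries <- 0L
      while (nrow(centers) < nLam && tries < 300L * nLam) {
        tries <- tries + 1L
        idx <- candidates[sample.int(length(candidates), 1)]
        cr <- (idx - 1L) %% size + 1L
        cc <- (idx - 1L) %/% size + 1L
        if (nrow(centers) == 0 ||
            min(sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2)) >=
            minSep)
          centers <- rbind(centers, c(cr, cc))
      }
      if (nrow(centers) < nLam)
        sgStop("sgPacking", "too many lamina nuclei for the available area")
      for (j in seq_len(nrow(centers))) {
        r0 <- min(max(rnorm(1, nucR, nucSd), 0.7 * nucR), 1.3 * nucR)
        label <- label + 1L
        nucLab <- renderNucleus(nucLab, centers[j, 1], centers[j, 2], r0,
                                irr, label)
        compartment <- c(compartment, "lamina")
      }
    }

    # ground-truth cells: band partition for epithelium, bounded expansion
    # for lamina cells (never into the crypt disc)
    cellLab <- matrix(0L, size, size)
    if (nEpi > 0) {
      epiNuc <- nucLab; epiNuc[epiNuc > nEpi] <- 0L
      cellLab <- nearestNucleusPartition(epiNuc, bandMask)
    }
    if (label > nEpi) {
      lamNuc <- nucLab; lamNuc[lamNuc <= nEpi] <- 0L
      lamCells <- expandCellsPcp(lamNuc, cellExpansion,
                                 forbidden = filledMask)
      cellLab[lamCells > 0] <- lamCells[lamCells > 0]
    }

    # spots: Poisson counts per cell and compartment, rendered as discs with
    # a minimum center separation so zero-noise counts are unambiguous
    spotLab <- matrix(0L, size, size)
    marker <- matrix(0, size, size)
    marker[cellLab > 0] <- baseline
    spotSep <- 2 * spotRad + 1.5
    spotCenters <- matrix(numeric(0), 0, 2)
    info <- data.frame(cell_id = seq_len(label), compartment = compartment,
                       n_spots_total = 0L, n_spots_nuclear = 0L,
                       n_spots_cytoplasmic = 0L)
    spotId <- 0L
    h <- size
    for (L in seq_len(label)) {
      nucIdx <- which(nucLab == L)
      cytIdx <- which(cellLab == L & nucLab == 0L)
      for (compTag in c("nucleus", "cytoplasm")) {
        lambda <- if (compTag == "nucleus") rateN else rateC
        pool <- if (compTag == "nucleus") nucIdx else cytIdx
        nWant <- rpois(1, lambda)
        if (nWant == 0 || length(pool) == 0) next
        placed <- 0L
        tries <- 0L
        while (placed < nWant && tries < 200L * nWant) {
          tries <- tries + 1L
          idx <- pool[sample.int(length(pool), 1)]
          cr <- (idx - 1L) %% h + 1L
          cc <- (idx - 1L) %/% h + 1L
          if (nrow(spotCenters) > 0 &&
              min(sqrt((spotCenters[, 1] - cr)^2 +
                       (spotCenters[, 2] - cc)^2)) < spotSep) next
          spotCenters <- rbind(spotCenters, c(cr, cc))
          spotId <- spotId + 1L
          placed <- placed + 1L
          rr <- max(1L, floor(cr - spotRad)):min(h, ceiling(cr + spotRad))
          ccn <- max(1L, floor(cc - spotRad)):min(h, ceiling(cc + spotRad))
          dd <- outer((rr - cr)^2, rep(1, length(ccn))) +
            outer(rep(1, length(rr)), (ccn - cc)^2)
          disc <- dd <= spotRad^2
          subS <- spotLab[rr, ccn, drop = FALSE]
          subS[disc] <- spotId
          spotLab[rr, ccn] <- subS
          subM <- marker[rr, ccn, drop = FALSE]
          subM[disc] <- spotInt
          marker[rr, ccn] <- subM
        }
        if (compTag == "nucleus")
          info$n_spots_nuclear[L] <- placed
        else
          info$n_spots_cytoplasmic[L] <- placed
      }
    }
    info$n_spots_total <- info$n_spots_nuclear + info$n_spots_cytoplasmic

    nucShape <- measureShape(nucLab)
    info$nucleus_area <- nucShape$area[match(info$cell_id,
                                             nucShape$object_id)]
    info$centroid_row <- nucShape$centroid_row[match(info$cell_id,
                                                     nucShape$object_id)]
    info$centroid_col <- nucShape$centroid_col[match(info$cell_id,
                                                     nucShape$object_id)]

    truth <- new("SceneTruth", nuclei = nucLab, cells = cellLab,
                 spots = spotLab, cellInfo = info, group = spec@group)

    nuclear <- spec@nuclearIntensity * (nucLab > 0)
    membrane <- spec@membraneIntensity * bandMask
    chans <- list(nuclear = nuclear * 1, membrane = membrane * 1,
                  marker = marker)
    chans <- lapply(chans, function(g) {
      if (spec@blurSigma > 0) g <- asMat(EBImage::gblur(g, spec@blurSigma))
      if (spec@noiseSigma > 0)
        g <- g + matrix(rnorm(length(g), 0, spec@noiseSigma), nrow(g))
      clip01(g)
    })
    img <- MultichannelImage(chans,
                             imageId = sprintf("synthetic_%s_seed%d",
                                               spec@group, spec@seed))
    list(image = img, truth = truth)
  })
}

#' Degrade staining quality of a scene
#'
#' Simulates a poorly stained membrane channel: Gaussian blur plus contrast
#' compression about the channel mean. Nuclear and marker channels are left
#' untouched, matching the observation that segmentation accuracy tracks the
#' membrane-marker staining quality.
#'
#' @param image [MultichannelImage-class].
#' @param blurSigma Gaussian blur sigma in pixels (>= 0).
#' @param contrastFactor multiplicative contrast compression in \code{(0, 1]}
#'   (1 = unchanged).
#' @return Degraded [MultichannelImage-class].
#' @export
degradeQuality <- function(image, blurSigma, contrastFactor) {
  if (contrastFactor <= 0 || contrastFactor > 1)
    sgStop("sgBadConfig", "contrastFactor must be in (0, 1]")
  if (blurSigma < 0) sgStop("sgBadConfig", "blurSigma must be >= 0")
  g <- channel(image, "membrane")
  mu <- mean(g)
  g <- mu + contrastFactor * (g - mu)
  if (blurSigma > 0) g <- asMat(EBImage::gblur(g, blurSigma))
  ch <- image@channels
  ch$membrane <- clip01(g)
  MultichannelImage(ch, imageId = image@imageId, pixelSize = image@pixelSize)
}
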