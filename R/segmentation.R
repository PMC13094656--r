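# Thresholding, primary/secondary/tertiary object segmentation and masking.
#
# All label maps are integer matrices with 0 = background, labeled with
# 8-connectivity and numbered in raster-scan order of each object's first
# pixel, so identical input and configuration give identical maps.

#' Otsu threshold of an intensity grid
#'
#' Histogram threshold maximizing the between-class variance over a fixed-bin
#' histogram of \code{[0, 1]}. The returned value is the upper edge of the
#' optimal cut bin; pixels strictly above it form the foreground. Ties are
#' resolved to the lowest cut, making the result deterministic.
#'
#' @param grid numeric matrix with intensities in \code{[0, 1]}.
#' @param nBins histogram resolution (default 256).
#' @return Threshold in \code{[0, 1]}.
#' @examples
#' g <- matrix(c(rep(0.2, 50), rep(0.8, 50)), 10)
#' otsuThreshold(g)
#' @export
otsuThreshold <- function(grid, nBins = 256L) {
  v <- as.numeric(asMat(grid))
  if (length(v) == 0 || anyNA(v))
    sgStop("sgDegenerateInput", "grid is empty or contains NA")
  if (max(v) == min(v))
    sgStop("sgDegenerateInput", "constant image has no Otsu threshold")
  nBins <- as.integer(nBins)
  bin <- pmin(pmax(floor(v * nBins), 0), nBins - 1L) + 1L
  h <- tabulate(bin, nbins = nBins)
  p <- h / sum(h)
  mids <- (seq_len(nBins) - 0.5) / nBins
  w1 <- cumsum(p)
  m1 <- cumsum(p * mids)
  mT <- m1[nBins]
  # between-class variance for a cut after bin k
  bcv <- (mT * w1 - m1)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- -Inf
  bcv[nBins] <- -Inf
  k <- which.max(bcv)
  k / nBins
}

# Threshold per configuration; manual overrides Otsu.
configThreshold <- function(grid, cfg) {
  if (cfg@thresholdMethod == "manual") cfg@manualThreshold
  else otsuThreshold(grid)
}

#' Identify primary objects (nuclei)
#'
#' CellProfiler-style primary object identification: Gaussian smoothing,
#' thresholding (Otsu or manual per configuration), hole filling, declumping
#' of touching objects by distance-transform maxima followed by seeded region
#' growing, then removal of objects whose equivalent diameter
#' \eqn{2\sqrt{A/\pi}} falls outside the configured band.
#'
#' @param grid normalized intensity grid (typically the nuclear channel).
#' @param cfg [PipelineConfig-class].
#' @param restrict optional boolean mask; segmentation is confined to it.
#' @return Integer label map.
#' @export
identifyPrimaryObjects <- function(grid, cfg = pipelineConfig(),
                                   restrict = NULL) {
  grid <- asMat(grid)
  sm <- if (cfg@smoothingSigma > 0)
    asMat(EBImage::gblur(grid, sigma = cfg@smoothingSigma)) else grid
  thr <- configThreshold(sm, cfg)
  mask <- sm > thr
  if (!is.null(restrict)) {
    checkSameDim(grid, restrict, "grid and restrict mask")
    mask <- mask & restrict
  }
  mask <- asMat(EBImage::fillHull(mask)) > 0
  if (!any(mask)) return(matrix(0L, nrow(grid), ncol(grid)))
  d <- asMat(EBImage::distmap(mask))
  # Seeds: local maxima of the distance map; maxima closer than the minimum
  # nucleus diameter are merged (connected plateaus become one seed).
  mx <- asMat(EBImage::dilate(d, discBrush(cfg@nucleusDiameterMin)))
  seedMask <- mask & (d >= mx - 1e-9)
  seeds <- label8(seedMask)
  labels <- asMat(EBImage::propagate(x = d, seeds = seeds, mask = mask,
                                     lambda = 0.05))
  labels <- matrix(as.integer(round(labels)), nrow(grid), ncol(grid))
  keepDiameterBand(labels, cfg@nucleusDiameterMin, cfg@nucleusDiameterMax)
}

# Drop labels whose equivalent diameter lies outside [dmin, dmax]; relabel.
keepDiameterBand <- function(labels, dmin, dmax) {
  areas <- labelAreas(labels)
  if (length(areas) == 0) return(relabelRaster(labels))
  eqd <- 2 * sqrt(areas / pi)
  drop <- as.integer(names(areas))[eqd < dmin | eqd > dmax]
  if (length(drop)) labels[labels %in% drop] <- 0L
  relabelRaster(labels)
}

#' Epithelial region mask from the membrane channel
#'
#' Smoothing, Otsu threshold, morphological closing (disc radius =
#' \code{ceiling(smoothingSigma)}), hole filling and removal of connected
#' regions smaller than \code{nucleusDiameterMin^2} pixels. The result covers
#' the membrane-marker-positive band together with its enclosed area (a crypt
#' annulus becomes a filled disc).
#'
#' @param membrane normalized membrane-marker grid.
#' @param cfg [PipelineConfig-class].
#' @return Logical matrix, \code{TRUE} inside the epithelial region.
#' @export
epithelialRegionMask <- function(membrane, cfg = pipelineConfig()) {
  membrane <- asMat(membrane)
  sm <- if (cfg@smoothingSigma > 0)
    asMat(EBImage::gblur(membrane, sigma = cfg@smoothingSigma)) else membrane
  thr <- otsuThreshold(sm)
  mask <- sm > thr
  brush <- discBrush(max(1, ceiling(cfg@smoothingSigma)))
  mask <- asMat(EBImage::closing(mask, brush)) > 0
  mask <- asMat(EBImage::fillHull(mask)) > 0
  lab <- label8(mask)
  areas <- labelAreas(lab)
  small <- as.integer(names(areas))[areas < cfg@nucleusDiameterMin^2]
  if (length(small)) mask[lab %in% small] <- FALSE
  mask
}

#' Retain or discard objects by overlap with a region
#'
#' Majority-rule masking: with \code{mode = "keep_inside"} an object is
#' retained iff the fraction of its pixels inside the region is at least
#' \code{minFraction}; with \code{"keep_outside"} iff that fraction is below
#' \code{minFraction}. Retained objects keep their original labels and pixel
#' sets (objects are never clipped).
#'
#' @param objects integer label map.
#' @param region logical region mask of the same geometry.
#' @param mode \code{"keep_inside"} or \code{"keep_outside"}.
#' @param minFraction overlap fraction cut (default 0.5).
#' @return Label map containing only the retained objects.
#' @export
maskObjects <- function(objects, region, mode = c("keep_inside",
                                                  "keep_outside"),
                        minFraction = 0.5) {
  mode <- match.arg(mode)
  objects <- asMat(objects)
  frac <- objectRegionFraction(objects, region)
  keep <- if (mode == "keep_inside") frac >= minFraction
          else frac < minFraction
  drop <- as.integer(names(frac))[!keep]
  out <- matrix(as.integer(objects), nrow(objects), ncol(objects))
  if (length(drop)) out[out %in% drop] <- 0L
  out
}

#' Grow epithelial cell objects from nuclei (ECP secondary objects)
#'
#' Seeded region growing on the membrane-intensity landscape (membrane ridges
#' act as barriers), with the nuclei as seeds and growth confined to the
#' epithelial region. Every cell contains its seed nucleus entirely and keeps
#' its label; distinct cells are pixel-disjoint.
#'
#' @param nuclei nuclei label map, already masked to the epithelial region.
#' @param membrane normalized membrane grid.
#' @param region logical epithelial mask.
#' @param lambda regularization of the growing metric (0 = purely
#'   intensity-driven, large = purely geometric).
#' @return Cell label map with labels matching the seed nuclei.
#' @export
identifySecondaryCellsEcp <- function(nuclei, membrane, region,
                                      lambda = 0.05) {
  nuclei <- asMat(nuclei)
  checkSameDim(nuclei, membrane, "nuclei and membrane")
  checkSameDim(nuclei, region, "nuclei and region")
  if (max(nuclei) == 0) return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  mask <- region | nuclei > 0  # guarantee nucleus containment
  cells <- asMat(EBImage::propagate(x = asMat(membrane), seeds = nuclei,
                                    mask = mask, lambda = lambda))
  cells <- matrix(as.integer(round(cells)), nrow(nuclei), ncol(nuclei))
  cells[nuclei > 0] <- nuclei[nuclei > 0]
  cells
}

#' Expand lamina propria cells from nuclei by a fixed distance (PCP)
#'
#' Each nucleus is dilated by Euclidean distance up to \code{distance} pixels;
#' contested pixels go to the nearest seed (ties to the lower nucleus label).
#' Pixels inside the forbidden region (the epithelium) are never assigned,
#' but every nucleus is retained inside its own cell.
#'
#' @param nuclei nuclei label map.
#' @param distance expansion distance in pixels (>= 0).
#' @param forbidden optional logical mask of pixels that must not be claimed.
#' @return Cell label map with labels matching the nuclei.
#' @export
expandCellsPcp <- function(nuclei, distance, forbidden = NULL) {
  if (distance < 0)
    sgStop("sgNegativeDistance", "expansion distance must be >= 0")
  nuclei <- asMat(nuclei)
  h <- nrow(nuclei); w <- ncol(nuclei)
  ids <- labelIds(nuclei)
  out <- matrix(0L, h, w)
  if (length(ids) == 0) return(out)
  if (!is.null(forbidden)) checkSameDim(nuclei, forbidden, "nuclei/forbidden")
  bestD <- matrix(Inf, h, w)
  bestL <- matrix(0L, h, w)
  for (L in ids) {  # ascending labels: strict '<' gives ties to lower label
    dL <- asMat(EBImage::distmap(nuclei != L))
    upd <- dL < bestD
    bestD[upd] <- dL[upd]
    bestL[upd] <- L
  }
  claim <- bestD <= distance
  if (!is.null(forbidden)) claim <- claim & !forbidden
  out[claim] <- bestL[claim]
  out[nuclei > 0] <- nuclei[nuclei > 0]
  out
}

#' Derive cytoplasm (tertiary objects)
#'
#' For every label L, cytoplasm(L) = cell(L) minus nucleus(L), as a pixel-set
#' identity. Cells whose cytoplasm comes out empty are allowed and flagged.
#'
#' @param cells cell label map.
#' @param nuclei nucleus label map with matching labels.
#' @return List with \code{labels} (cytoplasm label map) and
#'   \code{emptyCytoplasm} (integer vector of flagged cell labels).
#' @export
deriveCytoplasm <- function(cells, nuclei) {
  cells <- asMat(cells); nuclei <- asMat(nuclei)
  checkSameDim(cells, nuclei, "cells and nuclei")
  cyto <- matrix(as.integer(cells), nrow(cells), ncol(cells))
  cyto[nuclei > 0] <- 0L
  cellIdsV <- labelIds(cells)
  empty <- setdiff(cellIdsV, labelIds(cyto))
  list(labels = cyto, emptyCytoplasm = as.integer(empty))
}

#' Nucleus-to-cell mapping of a segmentation
#'
#' @param nuclei,cells matching label maps.
#' @return data.frame with \code{nucleus_id}, \code{cell_id} (identical by
#'   construction in both pipelines, retained for auditability).
#' @export
nucleusToCell <- function(nuclei, cells) {
  ids <- intersect(labelIds(nuclei), labelIds(cells))
  data.frame(nucleus_id = ids, cell_id = ids)
}
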