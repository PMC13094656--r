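# Lamina propria exclusion rules with full audit accounting: oversized cells
# (likely mis-segmentation), cells overlapping the epithelial region (treated
# as epithelial cells), and cells touching the image border.

newAudit <- function(ids) {
  n <- length(ids)
  data.frame(object_id = as.integer(ids), removed = rep(FALSE, n),
             reason = rep("none", n), area = rep(NA_real_, n),
             overlap_fraction = rep(NA_real_, n), stringsAsFactors = FALSE)
}

#' Filter oversized objects
#'
#' The mean area is computed once over all cells in the image (candidate
#' included); a cell is removed iff its area exceeds \code{factor} times that
#' mean. One-sided by design: only "too large" indicates incorrect
#' (under-)segmentation; small cells are legitimate.
#'
#' @param areas named numeric vector (names = object ids) or data.frame with
#'   columns \code{object_id} and \code{area}.
#' @param factor removal threshold as a multiple of the mean area (default 3).
#' @return FilterAudit data.frame.
#' @export
filterByArea <- function(areas, factor = 3) {
  if (is.data.frame(areas)) {
    a <- areas$area
    ids <- areas$object_id
  } else {
    a <- as.numeric(areas)
    ids <- as.integer(names(areas))
  }
  if (length(a) == 0) sgStop("sgZeroCells", "no cells with measured area")
  mu <- mean(a)
  audit <- newAudit(ids)
  audit$area <- a
  rm <- a > factor * mu
  audit$removed <- rm
  audit$reason[rm] <- "oversize"
  audit
}

#' Filter objects overlapping the epithelial region
#'
#' A cell is removed iff the fraction of its pixels inside the epithelial
#' region exceeds \code{maxFraction}: such cells are considered intestinal
#' epithelial cells, not lamina propria cells.
#'
#' @param cells cell label map.
#' @param region logical epithelial mask.
#' @param maxFraction maximum tolerated overlap fraction (default 0.5).
#' @return FilterAudit data.frame.
#' @export
filterByEpithelialOverlap <- function(cells, region, maxFraction = 0.5) {
  frac <- objectRegionFraction(asMat(cells), region)
  audit <- newAudit(as.integer(names(frac)))
  audit$overlap_fraction <- as.numeric(frac)
  rm <- audit$overlap_fraction > maxFraction
  audit$removed <- rm
  audit$reason[rm] <- "epithelial_overlap"
  audit
}

#' Filter objects touching the image border
#'
#' A cell is removed iff any of its pixels lies on row 0, column 0, the last
#' row or the last column (0-based convention).
#'
#' @param cells cell label map.
#' @return FilterAudit data.frame.
#' @export
filterBorderObjects <- function(cells) {
  cells <- asMat(cells)
  ids <- labelIds(cells)
  audit <- newAudit(ids)
  if (length(ids) == 0) return(audit)
  h <- nrow(cells); w <- ncol(cells)
  borderLabs <- unique(c(cells[1, ], cells[h, ], cells[, 1], cells[, w]))
  rm <- audit$object_id %in% borderLabs[borderLabs > 0]
  audit$removed <- rm
  audit$reason[rm] <- "border"
  audit
}

#' Apply the full lamina propria filter chain
#'
#' Reasons are evaluated in the fixed order oversize, epithelial overlap,
#' border; the first matching reason is recorded so every removal has exactly
#' one auditable cause. Filtering is a pure subset operation: kept plus
#' removed reconstruct the input exactly.
#'
#' @param cells cell label map.
#' @param region logical epithelial mask.
#' @param areas per-cell areas as accepted by [filterByArea()]; defaults to
#'   pixel counts of \code{cells}.
#' @param cfg [PipelineConfig-class] supplying \code{areaFilterFactor} and
#'   \code{epcamOverlapMax}.
#' @return List with \code{audit} (combined FilterAudit), \code{kept}
#'   (label map of surviving cells) and \code{counts} (removals per reason).
#' @export
applyObjectFilters <- function(cells, region, areas = NULL,
                               cfg = pipelineConfig()) {
  cells <- asMat(cells)
  if (is.null(areas)) areas <- labelAreas(cells)
  aud1 <- filterByArea(areas, cfg@areaFilterFactor)
  aud2 <- filterByEpithelialOverlap(cells, region, cfg@epcamOverlapMax)
  aud3 <- filterBorderObjects(cells)
  audit <- aud1
  audit$overlap_fraction <- aud2$overlap_fraction[match(audit$object_id,
                                                        aud2$object_id)]
  take2 <- !audit$removed & aud2$removed[match(audit$object_id,
                                               aud2$object_id)]
  audit$removed[take2] <- TRUE
  audit$reason[take2] <- "epithelial_overlap"
  take3 <- !audit$removed & aud3$removed[match(audit$object_id,
                                               aud3$object_id)]
  audit$removed[take3] <- TRUE
  audit$reason[take3] <- "border"
  kept <- cells
  drop <- audit$object_id[audit$removed]
  if (length(drop)) kept[kept %in% drop] <- 0L
  counts <- c(oversize = sum(audit$reason == "oversize"),
              epithelial_overlap = sum(audit$reason == "epithelial_overlap"),
              border = sum(audit$reason == "border"),
              kept = sum(!audit$removed))
  list(audit = audit, kept = kept, counts = counts)
}
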