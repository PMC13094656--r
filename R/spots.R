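# Marker spot detection, parent attribution and positivity classification.

#' Detect marker spots
#'
#' Threshold (Otsu or manual per configuration), 8-connected components, and
#' removal of components whose area lies outside the configured spot band.
#' Spots are deliberately not declumped.
#'
#' @param marker normalized marker grid.
#' @param cfg [PipelineConfig-class] supplying the threshold mode and the
#'   \code{[spotAreaMin, spotAreaMax]} band.
#' @param restrict optional logical mask limiting detection.
#' @return List with \code{labels} (spot label map) and \code{spots}
#'   (data.frame: \code{spot_id}, \code{area}, \code{centroid_row},
#'   \code{centroid_col}, \code{integrated_intensity}).
#' @export
detectSpots <- function(marker, cfg = pipelineConfig(), restrict = NULL) {
  marker <- asMat(marker)
  thr <- configThreshold(marker, cfg)
  mask <- marker > thr
  if (!is.null(restrict)) {
    checkSameDim(marker, restrict, "marker and restrict mask")
    mask <- mask & restrict
  }
  lab <- label8(mask)
  areas <- labelAreas(lab)
  drop <- as.integer(names(areas))[areas < cfg@spotAreaMin |
                                   areas > cfg@spotAreaMax]
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab <- relabelRaster(lab)
  ids <- labelIds(lab)
  if (length(ids) == 0) {
    return(list(labels = lab, spots = data.frame(
      spot_id = integer(0), area = integer(0), centroid_row = numeric(0),
      centroid_col = numeric(0), integrated_intensity = numeric(0))))
  }
  idx <- which(lab > 0)
  L <- lab[idx]
  h <- nrow(lab)
  rows <- (idx - 1L) %% h + 1L
  cols <- (idx - 1L) %/% h + 1L
  area <- as.integer(tapply(L, L, length))
  list(labels = lab, spots = data.frame(
    spot_id = ids,
    area = area,
    centroid_row = as.numeric(tapply(rows, L, mean)),
    centroid_col = as.numeric(tapply(cols, L, mean)),
    integrated_intensity = as.numeric(tapply(marker[idx], L, sum))))
}

#' Assign child objects to parents by maximum overlap
#'
#' Each child object is assigned to the parent label covering the largest
#' number of its pixels; ties go to the lower parent label; children with no
#' parent overlap get \code{NA}. This is the parent-child rule under which a
#' spot straddling the nuclear edge is classified as nuclear when most of its
#' pixels lie on the nucleus.
#'
#' @param children,parents integer label maps of the same geometry.
#' @return data.frame with \code{child_id}, \code{parent_id} (NA when
#'   unassigned), \code{overlap} (pixels shared with the chosen parent).
#' @export
assignByMaxOverlap <- function(children, parents) {
  children <- asMat(children); parents <- asMat(parents)
  checkSameDim(children, parents, "children and parents")
  ids <- labelIds(children)
  out <- data.frame(child_id = ids,
                    parent_id = rep(NA_integer_, length(ids)),
                    overlap = rep(0L, length(ids)))
  if (length(ids) == 0) return(out)
  sel <- children > 0 & parents > 0
  if (any(sel)) {
    df <- data.frame(child = children[sel], parent = parents[sel])
    cnt <- stats::aggregate(rep(1L, nrow(df)),
                            by = list(child = df$child, parent = df$parent),
                            FUN = sum)
    names(cnt)[3] <- "n"
    # max count per child, tie -> lower parent label
    cnt <- cnt[order(cnt$child, -cnt$n, cnt$parent), ]
    best <- cnt[!duplicated(cnt$child), ]
    m <- match(out$child_id, best$child)
    hit <- !is.na(m)
    out$parent_id[hit] <- as.integer(best$parent[m[hit]])
    out$overlap[hit] <- as.integer(best$n[m[hit]])
  }
  out
}

#' Attribute spots to compartments and cells
#'
#' Computes the maximum-overlap assignment twice: once against the
#' nucleus/cytoplasm maps (subcellular compartment) and once against the
#' whole-cell map (cell of record).
#'
#' @param spotLabels spot label map from [detectSpots()].
#' @param nuclei,cytoplasm,cells label maps sharing cell labels.
#' @return data.frame with \code{spot_id}, \code{parent_cell},
#'   \code{parent_compartment} (\code{"nucleus"}, \code{"cytoplasm"} or NA).
#' @export
attributeSpots <- function(spotLabels, nuclei, cytoplasm, cells) {
  byCell <- assignByMaxOverlap(spotLabels, cells)
  byNuc <- assignByMaxOverlap(spotLabels, nuclei)
  byCyt <- assignByMaxOverlap(spotLabels, cytoplasm)
  comp <- ifelse(byNuc$overlap >= byCyt$overlap & byNuc$overlap > 0,
                 "nucleus",
                 ifelse(byCyt$overlap > 0, "cytoplasm", NA_character_))
  data.frame(spot_id = byCell$child_id,
             parent_cell = byCell$parent_id,
             parent_compartment = comp)
}

#' Summarize spots per cell and classify positivity
#'
#' Aggregates attributed spots per cell and compartment and sets the positive
#' flag: a cell is positive iff it carries at least
#' \code{cfg@minSpotsPositive} spots (default 2 granules).
#'
#' @param spots data.frame from [attributeSpots()] joined with spot areas
#'   (columns \code{spot_id}, \code{parent_cell}, \code{parent_compartment},
#'   and optionally \code{area}).
#' @param cfg [PipelineConfig-class].
#' @param cellIds integer vector of all cell labels; cells without spots are
#'   reported with zero counts.
#' @return data.frame: \code{cell_id}, \code{n_spots_total},
#'   \code{n_spots_nuclear}, \code{n_spots_cytoplasmic},
#'   \code{mean_spot_area}, \code{positive}.
#' @export
summarizeSpotsPerCell <- function(spots, cfg = pipelineConfig(),
                                  cellIds = integer(0)) {
  cellIds <- sort(unique(c(as.integer(cellIds),
                           spots$parent_cell[!is.na(spots$parent_cell)])))
  nC <- length(cellIds)
  out <- data.frame(cell_id = cellIds, n_spots_total = rep(0L, nC),
                    n_spots_nuclear = rep(0L, nC),
                    n_spots_cytoplasmic = rep(0L, nC),
                    mean_spot_area = rep(NA_real_, nC))
  assigned <- spots[!is.na(spots$parent_cell), , drop = FALSE]
  if (nrow(assigned)) {
    tot <- table(assigned$parent_cell)
    nuc <- table(assigned$parent_cell[assigned$parent_compartment ==
                                        "nucleus"])
    cyt <- table(assigned$parent_cell[assigned$parent_compartment ==
                                        "cytoplasm"])
    m <- match(names(tot), out$cell_id)
    out$n_spots_total[m] <- as.integer(tot)
    out$n_spots_nuclear[match(names(nuc), out$cell_id)] <- as.integer(nuc)
    out$n_spots_cytoplasmic[match(names(cyt), out$cell_id)] <-
      as.integer(cyt)
    if ("area" %in% names(assigned)) {
      ma <- tapply(assigned$area, assigned$parent_cell, mean)
      out$mean_spot_area[match(names(ma), out$cell_id)] <- as.numeric(ma)
    }
  }
  out$positive <- out$n_spots_total >= cfg@minSpotsPositive
  out
}

#' Percentage of positive cells
#'
#' \code{100 * (positive cells) / (total cells)}, the headline readout of the
#' lamina propria pipeline.
#'
#' @param summaries data.frame from [summarizeSpotsPerCell()].
#' @return Percentage in \code{[0, 100]}.
#' @export
percentPositive <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) == 0)
    sgStop("sgZeroCells", "percent positive is undefined for zero cells")
  100 * sum(summaries$positive) / nrow(summaries)
}

#' Brute-force spot counter (independent oracle)
#'
#' A naive pixel-scan flood-fill counter written independently of
#' [detectSpots()] (explicit stack, no morphology library), used as the
#' second method in agreement analyses and as a detection oracle in tests.
#'
#' @param marker normalized marker grid.
#' @param threshold foreground cut in \code{[0, 1]} (pixels strictly above).
#' @param areaBand length-2 vector \code{c(min, max)} of admissible component
#'   areas (pixels, 8-connectivity).
#' @return Integer spot count.
#' @export
bruteForceSpotCount <- function(marker, threshold, areaBand = c(1, Inf)) {
  m <- asMat(marker) > threshold
  h <- nrow(m); w <- ncol(m)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!m[i, j] || seen[i, j]) next
    # flood fill with an explicit stack
    stack <- list(c(i, j))
    seen[i, j] <- TRUE
    area <- 0L
    while (length(stack)) {
      px <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      area <- area + 1L
      for (di in -1:1) for (dj in -1:1) {
        ni <- px[1] + di; nj <- px[2] + dj
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            m[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
    if (area >= areaBand[1] && area <= areaBand[2]) count <- count + 1L
  }
  count
}
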