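# End-to-end orchestration of the epithelial (ECP) and lamina propria (PCP)
# stage sequences, with per-stage count manifests.

makeManifest <- function(pipeline, image, counts, cfg) {
  new("RunManifest", pipeline = pipeline, imageId = imageId(image),
      stageCounts = vapply(counts, as.integer, integer(1)),
      config = cfg,
      version = as.character(packageVersion("SGprofiler")),
      seed = cfg@rngSeed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

emptySpotResult <- function(h, w) {
  list(labels = matrix(0L, h, w),
       spots = data.frame(spot_id = integer(0), area = integer(0),
                          centroid_row = numeric(0),
                          centroid_col = numeric(0),
                          integrated_intensity = numeric(0)))
}

# A constant marker channel means no detectable signal: report zero spots
# instead of propagating the degenerate-threshold error.
detectSpotsOrEmpty <- function(marker, cfg, restrict) {
  marker <- asMat(marker)
  if (max(marker) == min(marker) && cfg@thresholdMethod == "otsu")
    return(emptySpotResult(nrow(marker), ncol(marker)))
  detectSpots(marker, cfg, restrict = restrict)
}

stageError <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("[%s] %s", stage, conditionMessage(e)),
      class = c("sgStageError", class(e)[class(e) != "condition"]),
      call = NULL))
  })
}

#' Run the epithelial pipeline (ECP)
#'
#' Stage sequence: primary nuclei, epithelial region mask, keep-inside
#' masking, secondary cell growth on the membrane landscape, tertiary
#' cytoplasm, marker spot detection restricted to the cells, maximum-overlap
#' attribution (both nucleus/cytoplasm and whole-cell), intensity, shape and
#' radial-distribution measurements.
#'
#' @param image [MultichannelImage-class] with nuclear, membrane and marker
#'   channels.
#' @param cfg [PipelineConfig-class].
#' @return List: \code{objects} (per-cell table), \code{spots} (per-spot
#'   table), \code{manifest} ([RunManifest-class]), plus the label maps
#'   (\code{nuclei}, \code{cells}, \code{cytoplasm}, \code{spotLabels}) and
#'   the \code{epithelialMask}.
#' @export
runECP <- function(image, cfg = pipelineConfig()) {
  for (role in c("nuclear", "membrane", "marker")) channel(image, role)
  nuc0 <- stageError("identify_nuclei",
                     identifyPrimaryObjects(channel(image, "nuclear"), cfg))
  region <- stageError("epithelial_mask",
                       epithelialRegionMask(channel(image, "membrane"), cfg))
  nuclei <- stageError("mask_nuclei",
                       maskObjects(nuc0, region, "keep_inside"))
  cells <- stageError("secondary_cells",
                      identifySecondaryCellsEcp(nuclei,
                                                channel(image, "membrane"),
                                                region))
  cy <- stageError("cytoplasm", deriveCytoplasm(cells, nuclei))
  det <- stageError("detect_spots",
                    detectSpotsOrEmpty(channel(image, "marker"), cfg,
                                       restrict = cells > 0))
  attrib <- attributeSpots(det$labels, nuclei, cy$labels, cells)
  spotTab <- merge(det$spots, attrib, by = "spot_id")
  summaries <- summarizeSpotsPerCell(spotTab, cfg, cellIds = labelIds(cells))

  markerInt <- measureIntensity(cells, channel(image, "marker"))
  nucInt <- measureIntensity(nuclei, channel(image, "marker"))
  cytInt <- measureIntensity(cy$labels, channel(image, "marker"))
  shape <- measureShape(nuclei)
  radial <- radialDistribution(channel(image, "marker"), nuclei, cells,
                               cy$labels, cfg@nRadialBins)

  objects <- summaries
  objects$cell_integrated_intensity <-
    markerInt$integrated_intensity[match(objects$cell_id,
                                         markerInt$object_id)]
  objects$cell_mean_intensity <-
    markerInt$mean_intensity[match(objects$cell_id, markerInt$object_id)]
  objects$nuclear_integrated_intensity <-
    nucInt$integrated_intensity[match(objects$cell_id, nucInt$object_id)]
  objects$cytoplasm_integrated_intensity <-
    cytInt$integrated_intensity[match(objects$cell_id, cytInt$object_id)]
  objects$empty_cytoplasm <- objects$cell_id %in% cy$emptyCytoplasm
  for (cl in setdiff(names(shape), "object_id"))
    objects[[paste0("nucleus_", cl)]] <-
      shape[[cl]][match(objects$cell_id, shape$object_id)]
  objects <- merge(objects, radial, by = "cell_id", all.x = TRUE)
  objects <- objects[order(objects$cell_id), ]
  rownames(objects) <- NULL

  manifest <- makeManifest("ecp", image, c(
    nuclei_initial = length(labelIds(nuc0)),
    epithelial_mask_area = sum(region),
    nuclei_masked = length(labelIds(nuclei)),
    cells = length(labelIds(cells)),
    cytoplasm = length(labelIds(cy$labels)),
    spots_detected = nrow(det$spots),
    spots_assigned = sum(!is.na(attrib$parent_cell))), cfg)

  list(objects = objects, spots = spotTab, manifest = manifest,
       nuclei = nuclei, cells = cells, cytoplasm = cy$labels,
       spotLabels = det$labels, epithelialMask = region)
}

#' Run the lamina propria pipeline (PCP)
#'
#' Stage sequence: primary nuclei, epithelial region mask, keep-outside
#' masking, fixed-distance cell expansion (never into the epithelium), spot
#' detection restricted to the cells, attribution, positivity classification
#' (at least \code{minSpotsPositive} spots), percent positive, the object
#' filter chain (oversize, epithelial overlap, border) with audit, and
#' nuclear morphometrics.
#'
#' The percentage of positive cells is computed over all cells before
#' filtering; the filtered table (column \code{kept}) and the audit allow any
#' post-filter recomputation.
#'
#' @param image [MultichannelImage-class].
#' @param cfg [PipelineConfig-class].
#' @return List: \code{objects}, \code{spots}, \code{percentPositive},
#'   \code{filterAudit}, \code{manifest}, label maps (\code{nuclei},
#'   \code{cells}, \code{cytoplasm}, \code{keptCells}, \code{spotLabels})
#'   and \code{epithelialMask}.
#' @export
runPCP <- function(image, cfg = pipelineConfig()) {
  for (role in c("nuclear", "membrane", "marker")) channel(image, role)
  nuc0 <- stageError("identify_nuclei",
                     identifyPrimaryObjects(channel(image, "nuclear"), cfg))
  region <- stageError("epithelial_mask",
                       epithelialRegionMask(channel(image, "membrane"), cfg))
  nuclei <- stageError("mask_nuclei",
                       maskObjects(nuc0, region, "keep_outside"))
  cells <- stageError("expand_cells",
                      expandCellsPcp(nuclei, cfg@expansionDistance,
                                     forbidden = region & !(nuclei > 0)))
  cy <- stageError("cytoplasm", deriveCytoplasm(cells, nuclei))

  empty <- length(labelIds(cells)) == 0
  det <- if (empty) {
    emptySpotResult(nrow(cells), ncol(cells))
  } else {
    stageError("detect_spots",
               detectSpotsOrEmpty(channel(image, "marker"), cfg,
                                  restrict = cells > 0))
  }
  attrib <- attributeSpots(det$labels, nuclei, cy$labels, cells)
  spotTab <- merge(det$spots, attrib, by = "spot_id")
  summaries <- summarizeSpotsPerCell(spotTab, cfg, cellIds = labelIds(cells))
  pct <- if (nrow(summaries) > 0) percentPositive(summaries) else NA_real_

  shape <- measureShape(nuclei)
  cellShape <- measureShape(cells)
  filt <- if (empty) {
    list(audit = newAudit(integer(0)), kept = cells,
         counts = c(oversize = 0L, epithelial_overlap = 0L, border = 0L,
                    kept = 0L))
  } else {
    applyObjectFilters(cells, region,
                       areas = data.frame(object_id = cellShape$object_id,
                                          area = cellShape$area),
                       cfg = cfg)
  }

  objects <- summaries
  objects$kept <- !objects$cell_id %in%
    filt$audit$object_id[filt$audit$removed]
  objects$filter_reason <-
    filt$audit$reason[match(objects$cell_id, filt$audit$object_id)]
  objects$cell_area <- cellShape$area[match(objects$cell_id,
                                            cellShape$object_id)]
  markerInt <- if (empty) NULL
               else measureIntensity(cells, channel(image, "marker"))
  if (!is.null(markerInt)) {
    objects$cell_integrated_intensity <-
      markerInt$integrated_intensity[match(objects$cell_id,
                                           markerInt$object_id)]
    objects$cell_mean_intensity <-
      markerInt$mean_intensity[match(objects$cell_id, markerInt$object_id)]
  }
  for (cl in setdiff(names(shape), "object_id"))
    objects[[paste0("nucleus_", cl)]] <-
      shape[[cl]][match(objects$cell_id, shape$object_id)]
  rownames(objects) <- NULL

  manifest <- makeManifest("pcp", image, c(
    nuclei_initial = length(labelIds(nuc0)),
    epithelial_mask_area = sum(region),
    nuclei_masked = length(labelIds(nuclei)),
    cells = length(labelIds(cells)),
    spots_detected = nrow(det$spots),
    spots_assigned = sum(!is.na(attrib$parent_cell)),
    cells_kept = unname(filt$counts["kept"])), cfg)

  list(objects = objects, spots = spotTab, percentPositive = pct,
       filterAudit = filt$audit, manifest = manifest,
       nuclei = nuclei, cells = cells, cytoplasm = cy$labels,
       keptCells = filt$kept, spotLabels = det$labels,
       epithelialMask = region)
}

#' Write pipeline outputs to a directory
#'
#' Per-object CSV, per-spot CSV, filter-audit CSV (PCP), label-map TIFFs and
#' a plain-text manifest snapshot.
#'
#' @param result list returned by [runECP()] or [runPCP()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
writeRunOutputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- result$manifest
  prefix <- file.path(dir, man@pipeline)
  exportObjectTable(result$objects, paste0(prefix, "_objects.csv"))
  exportObjectTable(result$spots, paste0(prefix, "_spots.csv"))
  if (!is.null(result$filterAudit))
    exportObjectTable(result$filterAudit, paste0(prefix, "_filter_audit.csv"))
  exportLabelMap(result$nuclei, paste0(prefix, "_nuclei.tif"))
  exportLabelMap(result$cells, paste0(prefix, "_cells.tif"))
  exportLabelMap(result$spotLabels, paste0(prefix, "_spots.tif"))
  con <- file(paste0(prefix, "_manifest.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("pipeline: %s", man@pipeline),
    sprintf("image_id: %s", man@imageId),
    sprintf("version: %s", man@version),
    sprintf("seed: %d", man@seed),
    sprintf("timestamp: %s", man@timestamp),
    "stage_counts:",
    sprintf("  %s: %d", names(man@stageCounts), man@stageCounts)), con)
  invisible(dir)
}

#' Export a segmentation overlay PNG
#'
#' Paints object outlines over a grayscale channel: nuclei, cells and spots
#' each in their own color.
#'
#' @param image [MultichannelImage-class].
#' @param result pipeline result list.
#' @param path output PNG path.
#' @param role background channel role.
#' @return Invisibly, the path.
#' @export
writeOverlay <- function(image, result, path, role = "marker") {
  bg <- EBImage::rgbImage(red = channel(image, role),
                          green = channel(image, role),
                          blue = channel(image, role))
  ov <- EBImage::paintObjects(EBImage::Image(result$cells), bg,
                              col = "#808080")
  ov <- EBImage::paintObjects(EBImage::Image(result$nuclei), ov,
                              col = "#00FFFF")
  ov <- EBImage::paintObjects(EBImage::Image(result$spotLabels), ov,
                              col = "#FF00FF")
  EBImage::writeImage(ov, path, type = "png")
  invisible(path)
}
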