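# Per-object intensity, size/shape and radial intensity-distribution
# measurements (MeasureObjectIntensity / MeasureObjectSizeShape /
# MeasureObjectIntensityDistribution analogs).

#' Per-object intensity measurements
#'
#' Integrated intensity is the sum of the grid over the object's pixels; mean
#' intensity is integrated / area, so mean x area = integrated exactly up to
#' float accumulation.
#'
#' @param objects integer label map.
#' @param grid intensity grid of the same geometry.
#' @return data.frame: \code{object_id}, \code{area},
#'   \code{integrated_intensity}, \code{mean_intensity}.
#' @export
measureIntensity <- function(objects, grid) {
  objects <- asMat(objects); grid <- asMat(grid)
  checkSameDim(objects, grid, "objects and grid")
  ids <- labelIds(objects)
  if (length(ids) == 0)
    return(data.frame(object_id = integer(0), area = integer(0),
                      integrated_intensity = numeric(0),
                      mean_intensity = numeric(0)))
  sel <- objects > 0
  L <- objects[sel]
  tot <- tapply(grid[sel], L, sum)
  n <- tapply(grid[sel], L, length)
  data.frame(object_id = ids, area = as.integer(n),
             integrated_intensity = as.numeric(tot),
             mean_intensity = as.numeric(tot) / as.numeric(n))
}

# Chain length of the outer 8-connected boundary via Moore neighbor tracing:
# orthogonal steps count 1, diagonal steps sqrt(2). `mask` holds one connected
# object. Sub-resolution objects are degenerate: a single pixel is assigned
# the crack perimeter of its unit square (4).
mooreBoundaryLength <- function(mask) {
  npix <- sum(mask)
  if (npix == 0) return(0)
  if (npix == 1) return(4)
  h <- nrow(mask); w <- ncol(mask)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- mask
  start <- NULL
  for (i in seq_len(h + 2L)) {
    j <- which(p[i, ])[1]
    if (!is.na(j)) { start <- c(i, j); break }
  }
  # clockwise in image coordinates (rows grow downward): W NW N NE E SE S SW
  dirs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  stepLen <- rep(c(1, sqrt(2)), 4)
  cur <- start
  bdir <- 1L               # backtrack is the (background) west neighbor
  perim <- 0
  firstMove <- NA_integer_
  maxIter <- 16L * npix + 16L
  for (iter in seq_len(maxIter)) {
    moved <- FALSE
    for (k in 1:8) {
      d <- (bdir + k - 1L) %% 8L + 1L
      ni <- cur[1] + dirs[d, 1]; nj <- cur[2] + dirs[d, 2]
      if (p[ni, nj]) {
        atStart <- cur[1] == start[1] && cur[2] == start[2]
        if (atStart && !is.na(firstMove) && d == firstMove)
          return(perim)    # cycle closed
        if (atStart && is.na(firstMove)) firstMove <- d
        perim <- perim + stepLen[d]
        dprev <- (d - 2L) %% 8L + 1L
        bp <- c(cur[1] + dirs[dprev, 1], cur[2] + dirs[dprev, 2])
        cur <- c(ni, nj)
        delta <- bp - cur
        bdir <- which(dirs[, 1] == delta[1] & dirs[, 2] == delta[2])
        moved <- TRUE
        break
      }
    }
    if (!moved) return(max(perim, 1))
  }
  max(perim, 1)
}

#' Per-object size and shape measurements
#'
#' For each object: area (pixel count), perimeter (weighted chain code on the
#' outer 8-connected boundary, orthogonal steps 1 and diagonal steps
#' \eqn{\sqrt 2}), form factor \eqn{4\pi A / P^2} (1 for a circle in the
#' continuous limit), radius (mean Euclidean distance of object pixels to the
#' closest pixel outside the object, i.e. the mean of the distance transform),
#' and compactness \eqn{2\pi \cdot \mathrm{msd} / A} where msd is the mean
#' squared pixel distance from the centroid -- normalized so a perfect disc
#' scores exactly 1 and irregular or elongated shapes score above 1.
#'
#' Objects touching the image border are measured as-is but carry a
#' \code{touches_border} flag (the lamina pipeline removes them downstream).
#' Shape metrics of objects only a few pixels wide are intrinsically coarse.
#'
#' @param objects integer label map.
#' @return data.frame: \code{object_id}, \code{area}, \code{perimeter},
#'   \code{form_factor}, \code{radius}, \code{compactness},
#'   \code{centroid_row}, \code{centroid_col}, \code{touches_border}.
#' @export
measureShape <- function(objects) {
  objects <- asMat(objects)
  ids <- labelIds(objects)
  nI <- length(ids)
  out <- data.frame(object_id = ids, area = rep(NA_integer_, nI),
                    perimeter = rep(NA_real_, nI),
                    form_factor = rep(NA_real_, nI),
                    radius = rep(NA_real_, nI),
                    compactness = rep(NA_real_, nI),
                    centroid_row = rep(NA_real_, nI),
                    centroid_col = rep(NA_real_, nI),
                    touches_border = rep(NA, nI))
  if (length(ids) == 0) return(out)
  h <- nrow(objects); w <- ncol(objects)
  for (k in seq_along(ids)) {
    idx <- which(objects == ids[k])
    rows <- (idx - 1L) %% h + 1L
    cols <- (idx - 1L) %/% h + 1L
    a <- length(idx)
    cr <- mean(rows); cc <- mean(cols)
    r0 <- max(1L, min(rows) - 1L); r1 <- min(h, max(rows) + 1L)
    c0 <- max(1L, min(cols) - 1L); c1 <- min(w, max(cols) + 1L)
    sub <- objects[r0:r1, c0:c1, drop = FALSE] == ids[k]
    P <- mooreBoundaryLength(sub)
    dm <- asMat(EBImage::distmap(sub))
    msd <- mean((rows - cr)^2 + (cols - cc)^2)
    out$area[k] <- a
    out$perimeter[k] <- P
    out$form_factor[k] <- 4 * pi * a / P^2
    out$radius[k] <- mean(dm[sub])
    out$compactness[k] <- 2 * pi * msd / a
    out$centroid_row[k] <- cr
    out$centroid_col[k] <- cc
    out$touches_border[k] <- any(rows == 1L | rows == h |
                                 cols == 1L | cols == w)
  }
  out
}

#' Radial intensity distribution over cytoplasm bins (FracAtD)
#'
#' The cytoplasm of each cell is subdivided into \code{nBins} radial rings by
#' the normalized depth \eqn{d = d_{nuc} / (d_{nuc} + d_{edge})}, where
#' \eqn{d_{nuc}} is the Euclidean distance to the cell's nucleus pixel set and
#' \eqn{d_{edge}} the distance to the nearest non-cell pixel; bin 1 is
#' perinuclear, the last bin peripheral. \code{FracAtD_b} is the fraction of
#' the marker intensity summed over the cytoplasm that falls in bin b;
#' \code{BinAreaFrac_b} the corresponding pixel-count fraction (the
#' area-normalization reference, since outer rings are larger).
#'
#' Cells with empty cytoplasm, or zero cytoplasmic marker intensity, get
#' \code{NA} fractions and are flagged.
#'
#' @param marker normalized marker grid.
#' @param nuclei,cells,cytoplasm label maps sharing cell labels.
#' @param nBins number of radial bins (default 3).
#' @return data.frame: \code{cell_id}, \code{FracAtD_1..nBins},
#'   \code{BinAreaFrac_1..nBins}, \code{flagged}.
#' @export
radialDistribution <- function(marker, nuclei, cells, cytoplasm, nBins = 3L) {
  nBins <- as.integer(nBins)
  if (nBins < 1L) sgStop("sgBadConfig", "nBins must be >= 1")
  marker <- asMat(marker); nuclei <- asMat(nuclei)
  cells <- asMat(cells); cytoplasm <- asMat(cytoplasm)
  checkSameDim(marker, cells, "marker and cells")
  ids <- labelIds(cells)
  fracCols <- paste0("FracAtD_", seq_len(nBins))
  areaCols <- paste0("BinAreaFrac_", seq_len(nBins))
  out <- data.frame(cell_id = ids)
  for (cl in c(fracCols, areaCols)) out[[cl]] <- NA_real_
  out$flagged <- FALSE
  h <- nrow(cells); w <- ncol(cells)
  for (k in seq_along(ids)) {
    L <- ids[k]
    idx <- which(cells == L)
    rows <- (idx - 1L) %% h + 1L
    cols <- (idx - 1L) %/% h + 1L
    r0 <- max(1L, min(rows) - 1L); r1 <- min(h, max(rows) + 1L)
    c0 <- max(1L, min(cols) - 1L); c1 <- min(w, max(cols) + 1L)
    cellM <- cells[r0:r1, c0:c1, drop = FALSE] == L
    nucM <- nuclei[r0:r1, c0:c1, drop = FALSE] == L
    cytM <- cytoplasm[r0:r1, c0:c1, drop = FALSE] == L
    if (!any(cytM) || !any(nucM)) {
      out$flagged[k] <- TRUE
      next
    }
    dEdge <- asMat(EBImage::distmap(cellM))
    dNuc <- asMat(EBImage::distmap(!nucM))
    dep <- dNuc[cytM] / (dNuc[cytM] + dEdge[cytM])
    bin <- pmin(floor(dep * nBins) + 1L, nBins)
    inten <- marker[r0:r1, c0:c1, drop = FALSE][cytM]
    totI <- sum(inten)
    aFrac <- tabulate(bin, nbins = nBins) / length(bin)
    out[k, areaCols] <- aFrac
    if (totI > 0) {
      iFrac <- as.numeric(tapply(inten, factor(bin, levels = seq_len(nBins)),
                                 sum))
      iFrac[is.na(iFrac)] <- 0
      out[k, fracCols] <- iFrac / totI
    } else {
      out$flagged[k] <- TRUE
    }
  }
  out
}
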