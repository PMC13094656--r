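# TIFF ingestion, normalization and CSV export.

#' Load a multichannel TIFF as a normalized MultichannelImage
#'
#' Reads a single- or multi-page TIFF and assigns channels to roles through an
#' explicit `channelMap` (roles are never inferred from color order, since
#' microscope exports vary). Integer data are normalized by the dtype
#' full scale (8-bit by 255, 16-bit by 65535); floating-point data are clipped
#' to \code{[0, 1]}. Channels are indexed across pages first, then across
#' sample planes within a page.
#'
#' Burned-in scale bars or annotation graphics are not detected and will
#' corrupt segmentation; export images without overlays.
#'
#' @param path path to a TIFF file.
#' @param channelMap named integer vector mapping roles to channel indices,
#'   e.g. \code{c(nuclear = 1, membrane = 2, marker = 3)}.
#' @param imageId identifier; defaults to the file name.
#' @param pixelSize optional micrometres per pixel.
#' @return A [MultichannelImage-class].
#' @examples
#' tf <- tempfile(fileext = ".tif")
#' tiff::writeTIFF(matrix(runif(64), 8), tf, bits.per.sample = 8)
#' img <- loadImage(tf, c(nuclear = 1))
#' @export
loadImage <- function(path, channelMap, imageId = basename(path),
                      pixelSize = NA_real_) {
  if (!file.exists(path))
    sgStop("sgMissingFile", sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  planes <- list()
  for (p in pages) {
    if (length(dim(p)) == 3) {
      for (k in seq_len(dim(p)[3])) planes[[length(planes) + 1L]] <- p[, , k]
    } else {
      planes[[length(planes) + 1L]] <- p
    }
  }
  if (is.null(names(channelMap)) || any(!nzchar(names(channelMap))))
    sgStop("sgChannelIndex", "channelMap must be a named role->index vector")
  channels <- list()
  for (role in names(channelMap)) {
    i <- as.integer(channelMap[[role]])
    if (is.na(i) || i < 1L || i > length(planes))
      sgStop("sgChannelIndex",
             sprintf("channel index %s for role '%s' out of range (1..%d)",
                     channelMap[[role]], role, length(planes)))
    channels[[role]] <- normalizeGrid(planes[[i]])
  }
  d <- dim(channels[[1]])
  for (role in names(channels))
    if (!identical(dim(channels[[role]]), d))
      sgStop("sgShapeMismatch", "selected channels have mismatched shapes")
  MultichannelImage(channels, imageId = imageId, pixelSize = pixelSize)
}

#' Normalize a raw intensity grid to [0, 1]
#'
#' Integer grids are divided by the full scale of their inferred bit depth
#' (255 when all values fit in 8 bits, 65535 otherwise); floating-point grids
#' are clipped to \code{[0, 1]}. Normalization is monotone and maps the
#' dtype's minimum/maximum to exactly 0/1.
#'
#' @param grid numeric matrix of raw intensities.
#' @return Numeric matrix in \code{[0, 1]}.
#' @export
normalizeGrid <- function(grid) {
  m <- asMat(grid)
  isInt <- is.integer(m) ||
    (is.numeric(m) && length(m) && all(m == round(m)) && max(m) > 1)
  if (isInt) {
    scale <- if (max(m) <= 255) 255 else 65535
    m <- m / scale
  }
  storage.mode(m) <- "double"
  clip01(m)
}

#' Export an object table as CSV
#'
#' RFC-4180 CSV, UTF-8, '.' decimal separator; one row per object, one column
#' per measurement. An empty table yields a header-only file. The round trip
#' through [readObjectTable()] preserves counts exactly and numeric fields to
#' better than 1e-6 relative error.
#'
#' @param table data.frame with one row per object.
#' @param path output path.
#' @return Invisibly, the path written.
#' @export
exportObjectTable <- function(table, path) {
  if (!is.data.frame(table))
    sgStop("sgBadTable", "table must be a data.frame")
  ok <- tryCatch({
    write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) sgStop("sgUnwritablePath", sprintf("cannot write: %s", path))
  invisible(path)
}

#' Read back an object table CSV
#' @param path CSV written by [exportObjectTable()].
#' @return data.frame.
#' @export
readObjectTable <- function(path) {
  if (!file.exists(path))
    sgStop("sgMissingFile", sprintf("file not found: %s", path))
  read.csv(path, fileEncoding = "UTF-8")
}

#' Write a label map as a 16-bit single-channel TIFF
#'
#' Labels are stored as intensity = label/65535, the conventional lossless
#' encoding for up to 65535 objects.
#'
#' @param labels integer label matrix (0 = background).
#' @param path output path.
#' @return Invisibly, the path.
#' @export
exportLabelMap <- function(labels, path) {
  labels <- asMat(labels)
  if (max(labels) > 65535)
    sgStop("sgLabelOverflow", "more than 65535 labels cannot be stored")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a label map written by exportLabelMap
#' @param path 16-bit TIFF path.
#' @return Integer label matrix.
#' @export
readLabelMap <- function(path) {
  if (!file.exists(path))
    sgStop("sgMissingFile", sprintf("file not found: %s", path))
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read manual counts for validation
#'
#' Two-column CSV with \code{image_id} and \code{count}.
#'
#' @param path CSV path.
#' @return data.frame with columns \code{image_id}, \code{count}.
#' @export
readManualCounts <- function(path) {
  if (!file.exists(path))
    sgStop("sgMissingFile", sprintf("file not found: %s", path))
  df <- read.csv(path)
  if (!all(c("image_id", "count") %in% names(df)))
    sgStop("sgBadTable", "manual counts need columns image_id, count")
  df
}
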