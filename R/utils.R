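# Internal helpers shared across modules.

#' @import methods
#' @importFrom stats rnorm rpois runif sd var median cor cor.test lm coef pt
#' @importFrom stats aggregate setNames
#' @importFrom utils write.csv read.csv packageVersion
NULL

# Named error conditions so callers can distinguish failure modes.
sgStop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "sgError"), call = call))
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Coerce EBImage Image objects back to base matrices.
asMat <- function(x) {
  if (is(x, "Image")) x <- EBImage::imageData(x)
  m <- as.matrix(x)
  dim(m) <- dim(x)[1:2]
  m
}

checkSameDim <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    sgStop("sgShapeMismatch", sprintf("%s have mismatched geometry", what))
  invisible(TRUE)
}

# Odd-sized disc brush with radius approximately r pixels.
discBrush <- function(r) {
  size <- 2L * as.integer(max(1, round(r))) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

# 8-connected labeling. EBImage::bwlabel is 4-connected, so labels that touch
# only diagonally are merged afterwards through their adjacency graph.
label8 <- function(mask) {
  mask <- asMat(mask) > 0
  lab <- asMat(EBImage::bwlabel(mask))
  n <- max(lab)
  if (n < 2L) return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # down-left diagonal
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  edges <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  out <- matrix(as.integer(lab), h, w)
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::gorder(g)))
    comp <- igraph::components(g)$membership[seq_len(n)]
    out[out > 0] <- as.integer(comp[out[out > 0]])
  }
  relabelRaster(out)
}

# Deterministic labels: renumber objects 1..n in raster-scan (row-major)
# order of each object's first pixel.
relabelRaster <- function(labels) {
  labels <- asMat(labels)
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L)
    return(matrix(0L, nrow(labels), ncol(labels)))
  h <- nrow(labels)
  idx <- which(labels > 0)
  rows <- (idx - 1L) %% h + 1L
  cols <- (idx - 1L) %/% h + 1L
  rowMajor <- (rows - 1L) * ncol(labels) + cols
  anchor <- tapply(rowMajor, labels[idx], min)
  newId <- integer(max(ids))
  newId[as.integer(names(anchor))] <- rank(anchor, ties.method = "first")
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[idx] <- newId[labels[idx]]
  out
}

labelIds <- function(labels) sort(unique(labels[labels > 0]))

# Pixel count per label, as a named vector over labelIds.
labelAreas <- function(labels) {
  ids <- labelIds(labels)
  tab <- tabulate(labels[labels > 0], nbins = if (length(ids)) max(ids) else 0)
  structure(tab[ids], names = ids)
}

# Fraction of each object's pixels falling inside a boolean region.
objectRegionFraction <- function(labels, region) {
  checkSameDim(labels, region, "label map and region")
  ids <- labelIds(labels)
  if (length(ids) == 0L) return(numeric(0))
  nb <- max(ids)
  tot <- tabulate(labels[labels > 0], nbins = nb)
  ins <- tabulate(labels[labels > 0 & region], nbins = nb)
  structure(ins[ids] / tot[ids], names = ids)
}

# Run an expression with a locally seeded RNG, restoring global state after.
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
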