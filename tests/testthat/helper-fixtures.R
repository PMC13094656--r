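# Shared fixtures and independent oracles, all built in code.

# --- geometric fixtures -----------------------------------------------------

# Filled disc of radius r on an n x n grid (pixel centers within radius).
makeDisc <- function(r, n = 2 * ceiling(r) + 16, center = (n + 1) / 2,
                     value = 1L) {
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  m <- matrix(0L, n, n)
  m[(rows - center)^2 + (cols - center)^2 <= r^2] <- value
  m
}

# Annulus (membrane-band analog) on an n x n grid.
makeAnnulus <- function(rin, rout, n, value = 1) {
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  d2 <- (rows - (n + 1) / 2)^2 + (cols - (n + 1) / 2)^2
  m <- matrix(0, n, n)
  m[d2 >= rin^2 & d2 <= rout^2] <- value
  m
}

# Radial distance grid from the image center.
radialGrid <- function(n) {
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  sqrt((rows - (n + 1) / 2)^2 + (cols - (n + 1) / 2)^2)
}

# --- cached synthetic scenes ------------------------------------------------

.sceneCache <- new.env(parent = emptyenv())

cleanScene <- function(seed, ...) {
  key <- paste0("s", seed, "_", paste(deparse(list(...)), collapse = ""))
  if (!exists(key, envir = .sceneCache))
    assign(key, generateScene(sceneSpec(seed = seed, noiseSigma = 0,
                                        blurSigma = 0, ...)),
           envir = .sceneCache)
  get(key, envir = .sceneCache)
}

labelIdsOf <- function(lab) sort(unique(lab[lab > 0]))

# --- independent oracles ----------------------------------------------------

# Exhaustive between-class-variance scan over all histogram cut points,
# written longhand and independently of otsuThreshold().
otsuOracle <- function(v, nBins = 256L) {
  bin <- pmin(pmax(floor(v * nBins), 0), nBins - 1L) + 1L
  h <- tabulate(bin, nbins = nBins)
  mids <- (seq_len(nBins) - 0.5) / nBins
  best <- -Inf
  bestK <- NA_integer_
  for (k in seq_len(nBins - 1L)) {
    w1 <- sum(h[1:k])
    w2 <- sum(h) - w1
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(h[1:k] * mids[1:k]) / w1
    m2 <- sum(h[(k + 1):nBins] * mids[(k + 1):nBins]) / w2
    bcv <- w1 * w2 * (m1 - m2)^2
    if (bcv > best) {
      best <- bcv
      bestK <- k
    }
  }
  bestK / nBins
}

# Longhand per-pixel intensity summation.
intensityOracle <- function(labels, grid) {
  ids <- sort(unique(labels[labels > 0]))
  t(vapply(ids, function(L) {
    s <- 0
    n <- 0
    for (i in seq_len(nrow(labels))) for (j in seq_len(ncol(labels))) {
      if (labels[i, j] == L) {
        s <- s + grid[i, j]
        n <- n + 1
      }
    }
    c(id = L, integrated = s, mean = s / n)
  }, numeric(3)))
}

# Longhand Bland-Altman from first principles.
blandAltmanOracle <- function(a, b, multiplier = 1.96) {
  d <- a - b
  n <- length(d)
  bias <- sum(d) / n
  s <- sqrt(sum((d - bias)^2) / (n - 1))
  list(bias = bias, sd = s, lo = bias - multiplier * s,
       hi = bias + multiplier * s)
}

# Longhand OLS via the normal equations plus the Pearson r definition.
regressionOracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * sum(y^2) - sy^2))
  list(slope = slope, intercept = intercept, r = r)
}

# Longhand Pearson correlation with t-based p-value.
corOracle <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2))
}

# Match pipeline objects to ground-truth nuclei by nearest centroid.
matchToTruth <- function(objects, truthInfo, maxDist = 3) {
  vapply(seq_len(nrow(truthInfo)), function(i) {
    d <- sqrt((objects$nucleus_centroid_row - truthInfo$centroid_row[i])^2 +
              (objects$nucleus_centroid_col - truthInfo$centroid_col[i])^2)
    j <- which.min(d)
    if (length(j) && d[j] <= maxDist) j else NA_integer_
  }, integer(1))
}
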