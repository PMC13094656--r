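# Thresholding, nuclei identification, masking, cell growth and cytoplasm.

test_that("Otsu threshold separates a two-delta histogram", {
  g <- matrix(c(rep(0.2, 50), rep(0.8, 50)), 10)
  thr <- otsuThreshold(g)
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.8)
  g2 <- matrix(c(rep(0.1, 90), rep(0.9, 10)), 10)
  expect_equal(otsuThreshold(g2), otsuOracle(as.numeric(g2)))
})

test_that("Otsu threshold equals the exhaustive between-class-variance scan", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(50:400, 1)
    v <- switch(sample(3, 1),
                runif(n),
                pmin(pmax(c(rnorm(n %/% 2, 0.3, 0.08),
                            rnorm(n - n %/% 2, 0.7, 0.1)), 0), 1),
                sample(seq(0, 1, by = 1 / 16), n, replace = TRUE))
    if (max(v) == min(v)) v[1] <- v[1] + 0.5
    expect_equal(otsuThreshold(matrix(v, 1)), otsuOracle(v))
  }
})

test_that("constant images raise a named degenerate-input error", {
  expect_error(otsuThreshold(matrix(0.4, 5, 5)), class = "sgDegenerateInput")
  expect_error(epithelialRegionMask(matrix(0, 32, 32)),
               class = "sgDegenerateInput")
  expect_error(identifyPrimaryObjects(matrix(0.7, 32, 32),
                                      pipelineConfig(smoothingSigma = 0)),
               class = "sgDegenerateInput")
})

test_that("a single in-band disc is recovered exactly", {
  disc <- makeDisc(8, 40)
  lab <- identifyPrimaryObjects(disc * 1.0, pipelineConfig(smoothingSigma = 0))
  expect_equal(sort(unique(as.integer(lab))), c(0L, 1L))
  expect_identical(lab > 0, disc > 0)
})

test_that("disjoint discs give two objects; overlapping discs declump", {
  n <- 64
  rows <- matrix(seq_len(n), n, n); cols <- t(rows)
  two <- matrix(0, n, n)
  two[(rows - 20)^2 + (cols - 20)^2 <= 64] <- 1
  two[(rows - 45)^2 + (cols - 45)^2 <= 64] <- 1
  cfg <- pipelineConfig(smoothingSigma = 0)
  expect_equal(length(unique(identifyPrimaryObjects(two, cfg)[
    identifyPrimaryObjects(two, cfg) > 0])), 2L)
  # 30%-of-radius overlap: centers 1.7 * r apart
  ov <- matrix(0, n, n)
  ov[(rows - 32)^2 + (cols - 25)^2 <= 64] <- 1
  ov[(rows - 32)^2 + (cols - 38.6)^2 <= 64] <- 1
  lab <- identifyPrimaryObjects(ov, cfg)
  sh <- measureShape(lab)
  expect_equal(nrow(sh), 2L)
  d1 <- min(sqrt((sh$centroid_row - 32)^2 + (sh$centroid_col - 25)^2))
  d2 <- min(sqrt((sh$centroid_row - 32)^2 + (sh$centroid_col - 38.6)^2))
  expect_lt(d1, 2)
  expect_lt(d2, 2)
})

test_that("epithelial mask fills a bright annulus to the outer disc", {
  n <- 96
  ann <- makeAnnulus(18, 30, n, value = 0.8)
  cfg <- pipelineConfig(smoothingSigma = 0)
  mask <- epithelialRegionMask(ann, cfg)
  # flood-fill oracle: the mask must cover the thresholded annulus and its
  # enclosed hole, i.e. the full outer disc
  outer <- radialGrid(n) <= 30
  expect_gte(sum(mask & outer) / sum(outer), 0.99)
  expect_lt(sum(mask & !outer) / sum(mask), 0.05)
})

test_that("epithelial mask covers ground-truth band pixels on clean scenes", {
  sc <- cleanScene(5)
  mask <- epithelialRegionMask(channel(sc$image, "membrane"),
                               pipelineConfig())
  band <- channel(sc$image, "membrane") > 0.5
  expect_gte(sum(mask & band) / sum(band), 0.99)
})

test_that("maskObjects applies the majority rule in both modes", {
  lab <- matrix(0L, 10, 10)
  lab[2:5, 2:6] <- 1L          # 20 px
  region <- matrix(FALSE, 10, 10)
  region[2:5, 2:3] <- TRUE     # 8 of 20 px inside -> fraction 0.4
  expect_equal(labelIdsOf(maskObjects(lab, region, "keep_inside")),
               integer(0))
  expect_equal(labelIdsOf(maskObjects(lab, region, "keep_outside")), 1L)
  region[2:5, 2:6] <- TRUE     # fraction 1
  expect_equal(labelIdsOf(maskObjects(lab, region, "keep_inside")), 1L)
  expect_equal(labelIdsOf(maskObjects(lab, region, "keep_outside")),
               integer(0))
})

test_that("retained objects keep their labels and pixel sets", {
  lab <- matrix(0L, 12, 12)
  lab[2:4, 2:4] <- 7L
  lab[8:10, 8:10] <- 9L
  region <- matrix(FALSE, 12, 12)
  region[1:6, 1:6] <- TRUE
  kept <- maskObjects(lab, region, "keep_inside")
  expect_identical(kept == 7L, lab == 7L)
  expect_false(any(kept == 9L))
})

test_that("secondary cells claim a uniform region and split at the midline", {
  # single nucleus: cell = entire reachable region
  nuc <- matrix(0L, 30, 30)
  nuc[14:16, 14:16] <- 1L
  region <- radialGrid(30) <= 12
  cells <- identifySecondaryCellsEcp(nuc, matrix(0.5, 30, 30), region)
  expect_true(all(cells[region] == 1L))
  # two nuclei in a uniform corridor: boundary within 1 px of equidistance
  nuc2 <- matrix(0L, 20, 60)
  nuc2[9:11, 14:16] <- 1L
  nuc2[9:11, 44:46] <- 2L
  cells2 <- identifySecondaryCellsEcp(nuc2, matrix(0.5, 20, 60),
                                      matrix(TRUE, 20, 60))
  boundary <- max(which(cells2[10, ] == 1L))
  expect_lte(abs(boundary - 30), 1)
  # empty nuclei -> empty cells, no error
  expect_equal(max(identifySecondaryCellsEcp(matrix(0L, 10, 10),
                                             matrix(0.5, 10, 10),
                                             matrix(TRUE, 10, 10))), 0L)
})

test_that("PCP expansion is exact Euclidean dilation with nearest-seed ties", {
  nuc <- makeDisc(5, 40)
  expect_identical(expandCellsPcp(nuc, 0), matrix(as.integer(nuc), 40, 40))
  cells <- expandCellsPcp(nuc, 3)
  # disc of radius 8 up to a +/- 1 px rasterization band
  expect_true(all(cells[makeDisc(7, 40) > 0] > 0))
  expect_false(any(cells[makeDisc(9, 40) == 0] > 0))
  # contested pixels go to the nearer nucleus (brute-force oracle)
  nuc2 <- matrix(0L, 24, 40)
  nuc2[12, 10] <- 1L
  nuc2[12, 20] <- 2L
  cells2 <- expandCellsPcp(nuc2, 8)
  idx <- which(cells2 > 0)
  rows <- (idx - 1L) %% 24 + 1L
  cols <- (idx - 1L) %/% 24 + 1L
  d1 <- sqrt((rows - 12)^2 + (cols - 10)^2)
  d2 <- sqrt((rows - 12)^2 + (cols - 20)^2)
  want <- ifelse(d1 < d2, 1L, ifelse(d2 < d1, 2L, 1L))  # tie -> lower label
  expect_identical(cells2[idx], want)
  expect_true(all(pmin(d1, d2) <= 8))
  expect_error(expandCellsPcp(nuc, -1), class = "sgNegativeDistance")
})

test_that("expansion never claims forbidden pixels but keeps nuclei", {
  nuc <- matrix(0L, 20, 20)
  nuc[9:11, 9:11] <- 1L
  forb <- matrix(FALSE, 20, 20)
  forb[, 12:20] <- TRUE
  cells <- expandCellsPcp(nuc, 5, forbidden = forb)
  expect_false(any(cells[forb & nuc == 0L] > 0))
  expect_true(all(cells[nuc == 1L] == 1L))
})

test_that("cytoplasm is the exact per-label set difference", {
  nuc <- makeDisc(5, 30)
  cell <- makeDisc(8, 30)
  cy <- deriveCytoplasm(cell, nuc)
  expect_equal(sum(cy$labels > 0), sum(cell > 0) - sum(nuc > 0))
  expect_false(any(cy$labels > 0 & nuc > 0))
  expect_identical((cy$labels > 0) | (nuc > 0), cell > 0)
  # cell == nucleus -> empty cytoplasm, flagged
  cy2 <- deriveCytoplasm(nuc, nuc)
  expect_equal(sum(cy2$labels), 0L)
  expect_equal(cy2$emptyCytoplasm, 1L)
})

test_that("per-label identities hold across a whole synthetic scene", {
  sc <- cleanScene(2)
  res <- runECP(sc$image)
  for (L in labelIdsOf(res$cells)) {
    nucSet <- res$nuclei == L
    cellSet <- res$cells == L
    cytSet <- res$cytoplasm == L
    expect_true(all(cellSet[nucSet]))              # nucleus within cell
    expect_false(any(cytSet & nucSet))             # disjoint
    expect_identical(cytSet | nucSet, cellSet)     # partition
    expect_equal(sum(cellSet), sum(nucSet) + sum(cytSet))
  }
})

test_that("segmentation is deterministic", {
  sc <- cleanScene(4)
  cfg <- pipelineConfig()
  a <- identifyPrimaryObjects(channel(sc$image, "nuclear"), cfg)
  b <- identifyPrimaryObjects(channel(sc$image, "nuclear"), cfg)
  expect_identical(a, b)
})
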