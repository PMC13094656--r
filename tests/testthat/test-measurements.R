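# Intensity, shape and radial-distribution measurements.

test_that("intensity measurements equal the per-pixel loop oracle", {
  lab <- matrix(0L, 16, 16)
  lab[3:7, 3:7] <- 1L
  lab[10:14, 9:14] <- 2L
  # constant field
  g <- matrix(0.5, 16, 16)
  res <- measureIntensity(lab, g)
  expect_equal(res$integrated_intensity, c(25 * 0.5, 30 * 0.5))
  expect_equal(res$mean_intensity, c(0.5, 0.5))
  # zero field
  res0 <- measureIntensity(lab, matrix(0, 16, 16))
  expect_equal(res0$integrated_intensity, c(0, 0))
  expect_equal(res0$mean_intensity, c(0, 0))
  # random field vs longhand loop
  set.seed(5)
  gr <- matrix(runif(256), 16)
  res1 <- measureIntensity(lab, gr)
  or <- intensityOracle(lab, gr)
  expect_equal(res1$integrated_intensity, unname(or[, "integrated"]))
  expect_equal(res1$mean_intensity, unname(or[, "mean"]))
  expect_equal(res1$mean_intensity * res1$area, res1$integrated_intensity,
               tolerance = 1e-12)
})

test_that("form factor matches analytic shapes and converges for discs", {
  # rasterized square: area L^2, chain perimeter 4(L-1); approaches pi/4
  sq <- matrix(0L, 60, 60)
  sq[11:50, 11:50] <- 1L
  shSq <- measureShape(sq)
  expect_equal(shSq$area, 1600L)
  expect_equal(shSq$perimeter, 4 * 39)
  expect_equal(shSq$form_factor, 4 * pi * 1600 / (4 * 39)^2, tolerance = 1e-12)
  expect_equal(shSq$form_factor, pi / 4, tolerance = 0.06)
  # disc convergence band for the fixed perimeter estimator
  for (r in c(10, 25, 60, 120, 200)) {
    ff <- measureShape(makeDisc(r))$form_factor
    expect_gte(ff, 0.88)
    expect_lte(ff, 1.05)
  }
})

test_that("disc compactness and radius match their continuous limits", {
  sh <- measureShape(makeDisc(100, 256))
  expect_equal(sh$compactness, 1, tolerance = 0.02)
  expect_equal(sh$radius, 100 / 3, tolerance = 1 / 33)   # within 1 px
  sh50 <- measureShape(makeDisc(50))
  expect_equal(sh50$compactness, 1, tolerance = 0.02)
  # irregularity increases compactness: a thin bar scores well above 1
  bar <- matrix(0L, 12, 20)
  bar[6, 5:13] <- 1L
  expect_gt(measureShape(bar)$compactness, 1.5)
})

test_that("shape metrics agree with a direct pixel-sum oracle on a toy", {
  lab <- makeDisc(9, 28)
  sh <- measureShape(lab)
  idx <- which(lab > 0)
  rows <- (idx - 1) %% 28 + 1
  cols <- (idx - 1) %/% 28 + 1
  expect_equal(sh$area, length(idx))
  expect_equal(sh$centroid_row, mean(rows))
  expect_equal(sh$centroid_col, mean(cols))
  msd <- mean((rows - mean(rows))^2 + (cols - mean(cols))^2)
  expect_equal(sh$compactness, 2 * pi * msd / length(idx))
  # radius: longhand minimum distance to any outside pixel
  out <- which(lab == 0)
  orow <- (out - 1) %% 28 + 1
  ocol <- (out - 1) %/% 28 + 1
  dmin <- vapply(seq_along(idx), function(i)
    min(sqrt((orow - rows[i])^2 + (ocol - cols[i])^2)), numeric(1))
  expect_equal(sh$radius, mean(dmin), tolerance = 1e-9)
  expect_false(sh$touches_border)
  lab[1, 14] <- 1L
  expect_true(measureShape(lab)$touches_border)
})

test_that("radial bins place a perinuclear point mass in bin 1", {
  n <- 60
  nuc <- makeDisc(8, n)
  cell <- makeDisc(24, n)
  cyt <- matrix(as.integer(cell > 0 & nuc == 0), n, n)
  marker <- matrix(0, n, n)
  ring <- radialGrid(n)
  marker[ring > 8 & ring <= 9.5] <- 1   # pixels adjacent to the nucleus
  rad <- radialDistribution(marker, nuc, cell, cyt, 3)
  expect_equal(rad$FracAtD_1, 1)
  expect_equal(rad$FracAtD_2 + rad$FracAtD_3, 0)
})

test_that("uniform marker makes FracAtD equal the bin area fractions", {
  n <- 80
  nuc <- makeDisc(10, n)
  cell <- makeDisc(32, n)
  cyt <- matrix(as.integer(cell > 0 & nuc == 0), n, n)
  marker <- matrix(0.6, n, n)
  rad <- radialDistribution(marker, nuc, cell, cyt, 3)
  fr <- unlist(rad[1, paste0("FracAtD_", 1:3)])
  ar <- unlist(rad[1, paste0("BinAreaFrac_", 1:3)])
  expect_equal(unname(fr), unname(ar))
  expect_equal(sum(fr), 1)
  expect_equal(sum(ar), 1)
})

test_that("concentric annulus bins match the analytic area fractions", {
  n <- 100
  nuc <- makeDisc(10, n)
  cell <- makeDisc(40, n)
  cyt <- matrix(as.integer(cell > 0 & nuc == 0), n, n)
  rad <- radialDistribution(matrix(0.5, n, n), nuc, cell, cyt, 3)
  # depth d = (r - 10) / 30 -> ring edges at r = 20 and 30
  analytic <- c(20^2 - 10^2, 30^2 - 20^2, 40^2 - 30^2) / (40^2 - 10^2)
  for (b in 1:3)
    expect_equal(rad[[paste0("FracAtD_", b)]], analytic[b], tolerance = 0.02)
})

test_that("radial fractions sum to 1 and survive relabeling on a scene", {
  sc <- cleanScene(2)
  res <- runECP(sc$image)
  rad <- radialDistribution(channel(sc$image, "marker"), res$nuclei,
                            res$cells, res$cytoplasm, 3)
  ok <- !rad$flagged
  sums <- unname(rowSums(rad[ok, paste0("FracAtD_", 1:3)]))
  expect_equal(sums, rep(1, sum(ok)))
  # permute labels consistently: per-cell fractions must be unchanged
  ids <- labelIdsOf(res$cells)
  perm <- setNames(rev(ids), ids)
  remap <- function(m) {
    out <- m
    out[m > 0] <- perm[as.character(m[m > 0])]
    out
  }
  rad2 <- radialDistribution(channel(sc$image, "marker"), remap(res$nuclei),
                             remap(res$cells), remap(res$cytoplasm), 3)
  rad2 <- rad2[match(perm[as.character(rad$cell_id)], rad2$cell_id), ]
  expect_equal(unname(as.matrix(rad2[, 2:7])), unname(as.matrix(rad[, 2:7])))
})

test_that("empty cytoplasm yields a flagged record with null fractions", {
  nuc <- makeDisc(5, 20)
  rad <- radialDistribution(matrix(0.5, 20, 20), nuc, nuc,
                            matrix(0L, 20, 20), 3)
  expect_true(rad$flagged)
  expect_true(all(is.na(rad[1, paste0("FracAtD_", 1:3)])))
})
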