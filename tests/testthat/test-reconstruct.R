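test_that("heat-map binarization matches the brute-force comparison oracle", {
  set.seed(16)
  h <- matrix(runif(12 * 10), 12, 10)
  h[6, 5] <- 2  # single peak
  m <- binarizeHeatmap(h, 0.5, largestComponent = FALSE)
  oracle <- matrix(0L, 12, 10)
  for (i in 1:12) for (j in 1:10) if (h[i, j] >= 0.5 * 2) oracle[i, j] <- 1L
  expect_identical(m, oracle)
})

test_that("binarization limits: constant maps, near-1 thresholds, empty maps", {
  expect_true(all(binarizeHeatmap(matrix(5, 4, 4), 0.4) == 1L))
  h <- matrix(runif(8 * 8, 0, 0.5), 8, 8); h[3, 6] <- 1
  m <- binarizeHeatmap(h, 0.999)
  expect_identical(which(m == 1L), which(h >= 0.999 * max(h)))
  expect_warning(m0 <- binarizeHeatmap(matrix(0, 4, 4), 0.4), "all-zero")
  expect_equal(sum(m0), 0)
  expect_error(binarizeHeatmap(h, 1.2), "relThreshold")
})

test_that("largest-component cleanup suppresses secondary activations", {
  h <- matrix(0, 10, 10)
  h[2:5, 2:5] <- 1     # 16 px blob
  h[8:9, 8:9] <- 1     # 4 px decoy blob
  m <- binarizeHeatmap(h, 0.5, largestComponent = TRUE)
  expect_equal(sum(m), 16)
  expect_true(all(m[2:5, 2:5] == 1L))
  full <- binarizeHeatmap(h, 0.5, largestComponent = FALSE)
  expect_equal(sum(full), 20)
})

test_that("back-projection intersection: rectangles give the matching cuboid", {
  shape <- c(7, 8, 9)
  cor <- matrix(0L, 9, 7); cor[3:5, 2:4] <- 1L     # z rows, x cols
  sag <- matrix(0L, 9, 8); sag[3:5, 6:7] <- 1L     # z rows, y cols
  rec <- maskData(reconstruct3d(cor, sag, shape))
  oracle <- array(0L, shape); oracle[2:4, 6:7, 3:5] <- 1L
  expect_identical(rec, oracle)
  # either projection empty -> empty volume
  expect_equal(sum(maskData(reconstruct3d(matrix(0L, 9, 7), sag, shape))), 0)
  expect_error(reconstruct3d(matrix(0L, 5, 5), sag, shape), "coronal")
})

test_that("back-projection matches the exhaustive voxel oracle on random masks", {
  set.seed(17)
  for (rep in 1:10) {
    shape <- c(8, 8, 8)
    cor <- matrix(rbinom(64, 1, 0.4), 8, 8)
    sag <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_identical(maskData(reconstruct3d(cor, sag, shape)),
                     bruteReconstruct(cor, sag, shape))
  }
})

test_that("reconstruction is exact for cuboids and conservative for convex shapes", {
  # exactness: a cuboid is fully recovered from its own projections
  shape <- c(12, 12, 16)
  truth <- array(0L, shape); truth[4:7, 6:9, 5:11] <- 1L
  pv <- petVolume(truth + 0)
  cor <- (mipData(computeMip(pv, "coronal")) > 0) + 0L
  sag <- (mipData(computeMip(pv, "sagittal")) > 0) + 0L
  rec <- maskData(reconstruct3d(cor, sag, shape))
  expect_equal(diceCoef(rec, truth), 1.0)
  # superset: an ellipsoid is contained in the prism of its projections
  el <- array(0L, shape)
  for (x in 1:12) for (y in 1:12) for (z in 1:16)
    if (((x - 6) / 4)^2 + ((y - 6) / 3)^2 + ((z - 8) / 6)^2 <= 1) el[x, y, z] <- 1L
  pv2 <- petVolume(el + 0)
  cor2 <- (mipData(computeMip(pv2, "coronal")) > 0) + 0L
  sag2 <- (mipData(computeMip(pv2, "sagittal")) > 0) + 0L
  rec2 <- maskData(reconstruct3d(cor2, sag2, shape))
  expect_true(all(rec2[el == 1L] == 1L))
})

test_that("SUV refinement applies the 40% rule inside the mask and is idempotent", {
  set.seed(18)
  shape <- c(16, 16, 16)
  centre <- c(8.3, 8.7, 8.1); sigma <- c(2.5, 3, 2.8); peak <- 9
  comp <- array(0, shape)
  for (x in 1:16) for (y in 1:16) for (z in 1:16)
    comp[x, y, z] <- peak * exp(-0.5 * sum(((c(x, y, z) - centre) / sigma)^2))
  vol <- petVolume(comp)
  prism <- array(0L, shape); prism[3:14, 3:14, 3:14] <- 1L
  refined <- refineBySuv(tumorMask3D(prism), vol, frac = 0.4)
  mx <- max(comp[prism == 1L])
  oracle <- array(0L, shape)
  oracle[prism == 1L & comp >= 0.4 * mx] <- 1L
  expect_identical(maskData(refined), oracle)
  expect_identical(maskData(refineBySuv(refined, vol, frac = 0.4)),
                   maskData(refined))
  # uniform intensities: nothing removed
  uni <- petVolume(array(2, shape))
  expect_identical(maskData(refineBySuv(tumorMask3D(prism), uni)), prism)
  expect_warning(refineBySuv(tumorMask3D(array(0L, shape)), vol), "empty")
})
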