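test_that("resampling an already-isotropic volume at the target spacing is the identity", {
  set.seed(1)
  v <- petVolume(array(runif(16^3), c(16, 16, 16)), spacing = 2)
  out <- resampleIsotropic(v, 2)
  expect_equal(volumeData(out), volumeData(v), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(volumeSpacing(out), c(2, 2, 2))
})

test_that("resampling preserves constants and computes output shape from physical extent", {
  v <- petVolume(array(3.7, c(5, 6, 7)), spacing = c(4, 4, 2))
  out <- resampleIsotropic(v, 2)
  # brute-force shape arithmetic: ceil(n * spacing / target) per axis
  expect_identical(dim(volumeData(out)),
                   as.integer(ceiling(c(5, 6, 7) * c(4, 4, 2) / 2)))
  expect_equal(range(volumeData(out)), c(3.7, 3.7), tolerance = 1e-12)
  expect_error(resampleIsotropic(v, -2), "positive")
})

test_that("nearest-neighbour mask resampling keeps masks binary", {
  m <- array(0L, c(8, 8, 8)); m[3:5, 3:5, 3:5] <- 1L
  out <- resampleMask(tumorMask3D(m), spacing = c(4, 4, 4), targetMm = 2)
  expect_identical(dim(maskData(out)), c(16L, 16L, 16L))
  expect_true(all(maskData(out) %in% c(0L, 1L)))
  expect_gt(sum(maskData(out)), 0)
})

test_that("SUV normalization clips to [0, 30], scales to [0, 1] and is idempotent", {
  v <- petVolume(array(c(0, 15, 30, 45, 7.5, 1, 2, 3), c(2, 2, 2)))
  n <- normalizeSuv(v)
  expect_equal(volumeData(n)[1, 1, 1], 0)
  expect_equal(volumeData(n)[2, 2, 1], 1)    # 45 clipped to 30 -> 1
  expect_equal(volumeData(n)[2, 1, 1], 0.5)  # 15 / 30
  expect_equal(volumeData(n)[1, 2, 1], 1)    # 30 -> 1
  expect_equal(volumeData(normalizeSuv(n)), volumeData(n))
})

test_that("MIPs match the exhaustive axis-max oracle on random volumes", {
  set.seed(42)
  for (rep in 1:20) {
    v <- array(runif(16^3), c(16, 16, 16))
    pv <- petVolume(v)
    for (view in c("coronal", "sagittal"))
      expect_equal(mipData(computeMip(pv, view)), bruteMip(v, view))
  }
})

test_that("a single bright voxel projects to a single bright pixel in both views", {
  v <- array(0, c(6, 7, 8)); v[3, 5, 7] <- 1
  cor <- mipData(computeMip(petVolume(v), "coronal"))
  sag <- mipData(computeMip(petVolume(v), "sagittal"))
  expect_equal(which(cor == 1, arr.ind = TRUE)[1, ], c(row = 7, col = 3))
  expect_equal(which(sag == 1, arr.ind = TRUE)[1, ], c(row = 7, col = 5))
  expect_equal(sum(cor > 0), 1L)
  expect_equal(sum(sag > 0), 1L)
})

test_that("the volume maximum survives projection in both views", {
  set.seed(3)
  v <- petVolume(array(runif(5 * 6 * 7), c(5, 6, 7)))
  expect_equal(max(mipData(computeMip(v, "coronal"))), max(volumeData(v)))
  expect_equal(max(mipData(computeMip(v, "sagittal"))), max(volumeData(v)))
})

test_that("normalization commutes with projection (monotone map vs max)", {
  set.seed(4)
  raw <- array(runif(8^3, 0, 40), c(8, 8, 8))
  v <- petVolume(raw)
  mipThenNorm <- pmin(mipData(computeMip(v, "coronal")), 30) / 30
  normThenMip <- mipData(computeMip(normalizeSuv(v), "coronal"))
  expect_equal(normThenMip, mipThenNorm, tolerance = 1e-12)
})

test_that("prior projection follows the view conventions and back-intersects at the voxel", {
  p <- priorPoint(c(3, 5, 7))
  expect_equal(projectPrior(p, "coronal"), c(row = 7, col = 3))
  expect_equal(projectPrior(p, "sagittal"), c(row = 7, col = 5))
  expect_error(projectPrior(p, "coronal", volumeShape = c(4, 4, 8)), "outside")
  # geometry: back-projecting the two 2D points intersects exactly at p
  shape <- c(6, 7, 8)
  cor <- matrix(0L, shape[3], shape[1]); cor[7, 3] <- 1L
  sag <- matrix(0L, shape[3], shape[2]); sag[7, 5] <- 1L
  rec <- maskData(reconstruct3d(cor, sag, shape))
  expect_equal(which(rec == 1L, arr.ind = TRUE)[1, ], c(dim1 = 3, dim2 = 5, dim3 = 7),
               ignore_attr = TRUE)
  expect_equal(sum(rec), 1L)
})

test_that("axis bookkeeping names the retained and collapsed axes per view", {
  expect_equal(unname(retainedAxes("coronal")), c("z", "x"))
  expect_equal(unname(retainedAxes("sagittal")), c("z", "y"))
  expect_equal(collapsedAxis("coronal"), "y")
  expect_equal(collapsedAxis("sagittal"), "x")
  expect_error(computeMip(petVolume(array(1, c(4, 4, 4))), "axial"))
})
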