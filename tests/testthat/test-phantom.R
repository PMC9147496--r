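test_that("cohort generation is bit-reproducible given the seed", {
  a <- generateCohort(smallPhantomSpec(3, seed = 7))
  b <- generateCohort(smallPhantomSpec(3, seed = 7))
  for (i in seq_along(a)) {
    expect_identical(volumeData(patientVolume(a[[i]])),
                     volumeData(patientVolume(b[[i]])))
    expect_identical(maskData(patientMask(a[[i]])), maskData(patientMask(b[[i]])))
    expect_identical(patientOutcome(a[[i]]), patientOutcome(b[[i]]))
  }
  c <- generateCohort(smallPhantomSpec(3, seed = 8))
  expect_false(identical(volumeData(patientVolume(a[[1]])),
                         volumeData(patientVolume(c[[1]]))))
})

test_that("ground-truth mask equals an independent 40%-of-max threshold of the tumour component", {
  co <- generateCohort(smallPhantomSpec(2, seed = 3, noiseSigma = 0,
                                        classBalance = 1))
  for (p in co) {
    prov <- patientMask(p)@provenance
    sh <- dim(volumeData(patientVolume(p)))
    # recompute the truncated Gaussian voxel by voxel from the recorded
    # generative parameters and threshold it from scratch
    oracle <- array(0L, sh)
    lo <- prov$cuboid["lo", ]; hi <- prov$cuboid["hi", ]
    comp <- array(0, sh)
    for (x in lo[1]:hi[1]) for (y in lo[2]:hi[2]) for (z in lo[3]:hi[3])
      comp[x, y, z] <- prov$peak *
        exp(-0.5 * (((x - prov$centre[1]) / prov$sigma[1])^2 +
                    ((y - prov$centre[2]) / prov$sigma[2])^2 +
                    ((z - prov$centre[3]) / prov$sigma[3])^2))
    thr <- 0.4 * max(comp)
    oracle[comp >= thr & comp > 0] <- 1L
    expect_identical(maskData(patientMask(p)), oracle)
  }
})

test_that("class draws respect the configured balance", {
  co <- generateCohort(phantomSpec(nPatients = 100, classBalance = 0.5,
                                   volumeShape = c(16, 16, 32), seed = 5))
  nLung <- sum(vapply(co, patientClass, 1L))
  # 99% binomial interval around 50
  expect_gte(nLung, qbinom(0.005, 100, 0.5))
  expect_lte(nLung, qbinom(0.995, 100, 0.5))
})

test_that("phantom invariants: prior in mask, centroid near prior, classes separable in x", {
  co <- generateCohort(smallPhantomSpec(12, seed = 9, noiseSigma = 0))
  nx <- 24
  for (p in co) {
    v <- priorVoxel(patientPrior(p))
    m <- maskData(patientMask(p))
    expect_identical(m[v[1], v[2], v[3]], 1L)
    idx <- which(m == 1L, arr.ind = TRUE)
    centroid <- colMeans(idx)
    expect_lt(max(abs(centroid - v)), 1 + 1e-9)
    # one tumour: mask voxels confined to the recorded bounding cuboid
    prov <- patientMask(p)@provenance
    expect_true(all(idx[, 1] >= prov$cuboid["lo", 1] & idx[, 1] <= prov$cuboid["hi", 1]))
    offCentre <- abs(v[1] - (nx + 1) / 2)
    if (patientClass(p) == 1L) expect_gt(offCentre, 3) else expect_lt(offCentre, 3)
  }
})

test_that("volume-median outcome rule is exactly recoverable at zero flip noise", {
  co <- generateCohort(smallPhantomSpec(10, seed = 2, outcomeFlipProb = 0))
  vols <- vapply(co, function(p) sum(maskData(patientMask(p))), 0L)
  expected <- as.integer(vols * 8 > median(vols * 8))  # 2mm voxels
  expect_identical(vapply(co, patientOutcome, 1L), expected)
})

test_that("invalid phantom specs are rejected with the offending field named", {
  expect_error(phantomSpec(nPatients = 0), "nPatients")
  expect_error(phantomSpec(spacing = c(2, -1, 2)), "spacing")
  expect_error(phantomSpec(classBalance = 1.5), "classBalance")
  expect_error(phantomSpec(tumorIntensity = c(5, 2)), "tumorIntensity")
})

test_that("cohorts round-trip through NIfTI and the manifest", {
  co <- generateCohort(smallPhantomSpec(3, seed = 4))
  dir <- withr::local_tempdir()
  manifest <- writeCohort(co, dir)
  expect_equal(nrow(manifest), 3L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- readCohort(dir)
  for (i in seq_along(co)) {
    expect_equal(volumeData(patientVolume(back[[i]])),
                 volumeData(patientVolume(co[[i]])), ignore_attr = TRUE)
    expect_identical(maskData(patientMask(back[[i]])),
                     maskData(patientMask(co[[i]])))
    expect_identical(priorVoxel(patientPrior(back[[i]])),
                     priorVoxel(patientPrior(co[[i]])))
    v <- priorVoxel(patientPrior(back[[i]]))
    expect_identical(maskData(patientMask(back[[i]]))[v[1], v[2], v[3]], 1L)
    expect_equal(volumeSpacing(patientVolume(back[[i]])), c(2, 2, 2))
  }
})
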