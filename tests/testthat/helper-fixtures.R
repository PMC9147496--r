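# Shared fixtures: small configurations and generated cohorts, built in
# code at test time and cached for the session.

tinyNetConfig <- function(input = c(16, 8)) {
  classifierConfig(inputShape = input, channels = c(2, 2), strides = c(2, 2),
                   denseWidths = c(6, 4))
}

smallNetConfig <- function() {
  # matches the 48 x 24 MIPs of the small phantom below
  classifierConfig(inputShape = c(48, 24), channels = c(4, 4, 8, 8),
                   strides = c(2, 1, 2, 1), denseWidths = c(16, 8))
}

smallPhantomSpec <- function(n = 8, seed = 1, ...) {
  phantomSpec(nPatients = n, volumeShape = c(24, 24, 48), seed = seed, ...)
}

.fixtureCache <- new.env(parent = emptyenv())

cachedSmallCohort <- function(n = 8, seed = 1) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateCohort(smallPhantomSpec(n, seed))
  .fixtureCache[[key]]
}

# Brute-force MIP oracle: explicit loops over retained coordinates.
bruteMip <- function(vol, view) {
  d <- dim(vol)
  if (view == "coronal") {
    out <- matrix(NA_real_, d[3], d[1])
    for (z in seq_len(d[3])) for (x in seq_len(d[1])) out[z, x] <- max(vol[x, , z])
  } else {
    out <- matrix(NA_real_, d[3], d[2])
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) out[z, y] <- max(vol[, y, z])
  }
  out
}

# Brute-force back-projection oracle: triple loop over voxels.
bruteReconstruct <- function(maskCor, maskSag, shape) {
  out <- array(0L, shape)
  for (x in seq_len(shape[1])) for (y in seq_len(shape[2])) for (z in seq_len(shape[3]))
    if (maskCor[z, x] > 0 && maskSag[z, y] > 0) out[x, y, z] <- 1L
  out
}
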