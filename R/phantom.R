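#' Describe a synthetic PET phantom cohort
#'
#' Builds the parameter object consumed by [generateCohort()]. The phantom
#' emulates the statistical structure the weakly supervised pipeline
#' assumes: a low-uptake body envelope, bright physiological decoys at
#' fixed anatomical-analogue positions (a "brain" near the top of the
#' volume, a "bladder" near the bottom, a "heart" left of the midline), and
#' exactly one class-dependent tumour blob per patient. Esophageal tumours
#' sit on the midline column, posterior of centre; lung tumours sit in a
#' lateral lobe, anterior of centre -- so cancer type is recoverable from
#' either projection, which is what lets an image-level classifier learn.
#' Decoys may be brighter than the tumour: telling pathological from
#' physiological uptake is exactly the confusion the prior-point distance
#' constraint exists to resolve.
#'
#' @param volumeShape voxel counts (x, y, z). The default 64 x 64 x 128
#'   yields 128 x 64 MIPs, matching the compact classifier configuration.
#' @param spacing voxel size in mm (recycled to 3).
#' @param nPatients cohort size.
#' @param classBalance fraction of lung-cancer patients.
#' @param tumorIntensity SUV range the tumour peak is drawn from.
#' @param decoyIntensity SUV range decoy peaks are drawn from; the default
#'   upper end exceeds the tumour range on purpose.
#' @param backgroundIntensity SUV of the body envelope.
#' @param noiseSigma additive Gaussian noise scale in SUV (clipped at 0).
#' @param outcomeRule `"volume_median"` (outcome 1 iff tumour volume above
#'   the cohort median) or `"none"`.
#' @param outcomeFlipProb probability each outcome label is flipped.
#' @param seed integer RNG seed; generation is bit-reproducible given it.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(nPatients = 2, seed = 1)
#' spec
#' @export
phantomSpec <- function(volumeShape = c(64, 64, 128), spacing = c(2, 2, 2),
                        nPatients = 60, classBalance = 0.5,
                        tumorIntensity = c(5, 12), decoyIntensity = c(8, 15),
                        backgroundIntensity = 1.5, noiseSigma = 0.15,
                        outcomeRule = "volume_median", outcomeFlipProb = 0.1,
                        seed = 1) {
  new("PhantomSpec",
      volumeShape = as.integer(volumeShape),
      spacing = rep(as.numeric(spacing), length.out = 3L),
      nPatients = as.integer(nPatients),
      classBalance = as.numeric(classBalance),
      tumorIntensity = as.numeric(tumorIntensity),
      decoyIntensity = as.numeric(decoyIntensity),
      backgroundIntensity = as.numeric(backgroundIntensity),
      noiseSigma = as.numeric(noiseSigma),
      outcomeRule = outcomeRule,
      outcomeFlipProb = as.numeric(outcomeFlipProb),
      seed = as.integer(seed))
}

# Additive spherical hotspot with quadratic falloff, peak `peak` at `centre`.
.addSphere <- function(vol, centre, radius, peak, coords) {
  r2 <- ((coords$x - centre[1])^2 + (coords$y - centre[2])^2 +
           (coords$z - centre[3])^2) / radius^2
  vol + peak * pmax(0, 1 - r2)
}

# Truncated anisotropic Gaussian tumour component on the full grid.
# Nonzero only inside the bounding cuboid centre +/- ceil(3 sigma).
.tumorComponent <- function(shape, centre, sigma, peak) {
  comp <- array(0, shape)
  lo <- pmax(1L, ceiling(centre - 3 * sigma))
  hi <- pmin(shape, floor(centre + 3 * sigma))
  ex <- exp(-0.5 * ((lo[1]:hi[1] - centre[1]) / sigma[1])^2)
  ey <- exp(-0.5 * ((lo[2]:hi[2] - centre[2]) / sigma[2])^2)
  ez <- exp(-0.5 * ((lo[3]:hi[3] - centre[3]) / sigma[3])^2)
  block <- peak * (ex %o% ey %o% ez)
  comp[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- block
  list(component = comp, cuboid = rbind(lo = lo, hi = hi))
}

#' Generate a synthetic PET cohort
#'
#' Draws `nPatients` phantoms from a [PhantomSpec-class]. Each patient's
#' ground-truth mask follows the clinical metabolic-tumour-volume protocol:
#' the noise-free tumour component is thresholded at 40% of its maximum
#' inside the tumour's bounding cuboid. The prior point is the tumour
#' centre voxel and always lies inside the ground-truth mask. Under the
#' `"volume_median"` rule, outcome is 1 iff the tumour volume exceeds the
#' cohort median, then flipped with probability `outcomeFlipProb`.
#'
#' The generative parameters of each tumour (centre, per-axis sigma, peak,
#' bounding cuboid) are recorded in the ground-truth mask's provenance so
#' that the mask can be re-derived independently.
#'
#' @param spec a [PhantomSpec-class].
#' @return list of [PhantomPatient-class], length `nPatients`.
#' @examples
#' cohort <- generateCohort(phantomSpec(nPatients = 2, volumeShape = c(24, 24, 48),
#'                                      seed = 7))
#' cohort[[1]]
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  .withSeed(spec@seed, function() {
    sh <- spec@volumeShape
    nx <- sh[1]; ny <- sh[2]; nz <- sh[3]
    coords <- list(
      x = array(seq_len(nx), sh),
      y = array(rep(rep(seq_len(ny), each = nx), nz), sh),
      z = array(rep(seq_len(nz), each = nx * ny), sh)
    )
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
    # Body envelope: elliptic cylinder spanning z, soft lateral edge.
    body2 <- ((coords$x - cx) / (0.46 * nx))^2 + ((coords$y - cy) / (0.46 * ny))^2
    envelope <- spec@backgroundIntensity * pmin(1, pmax(0, 2 - 2 * body2))
    decoyCentres <- list(
      brain   = c(cx, cy, 0.92 * nz),
      bladder = c(cx, cy, 0.08 * nz),
      heart   = c(0.40 * nx, 0.42 * ny, 0.58 * nz)
    )
    decoyRadius <- c(brain = 0.10 * nz, bladder = 0.06 * nz, heart = 0.055 * nz)

    patients <- vector("list", spec@nPatients)
    tumorVolumes <- numeric(spec@nPatients)
    for (i in seq_len(spec@nPatients)) {
      classLabel <- stats::rbinom(1L, 1L, spec@classBalance)
      # Low-frequency per-patient background modulation.
      ph <- stats::runif(2, 0, 2 * pi)
      bg <- envelope * (1 + 0.1 * sin(2 * pi * coords$z / nz + ph[1]) *
                          cos(2 * pi * coords$x / nx + ph[2]))
      vol <- bg
      for (d in names(decoyCentres)) {
        peak <- stats::runif(1, spec@decoyIntensity[1], spec@decoyIntensity[2])
        vol <- .addSphere(vol, decoyCentres[[d]], decoyRadius[d], peak, coords)
      }
      if (classLabel == 1L) {  # lung: lateral lobe, anterior
        side <- sample(c(-1, 1), 1L)
        centre <- c(cx + side * 0.25 * nx + stats::runif(1, -1.5, 1.5),
                    0.40 * ny + stats::runif(1, -2, 2),
                    stats::runif(1, 0.50, 0.75) * nz)
      } else {                 # esophageal: midline column, posterior
        centre <- c(cx + stats::runif(1, -1.5, 1.5),
                    0.62 * ny + stats::runif(1, -2, 2),
                    stats::runif(1, 0.45, 0.70) * nz)
      }
      sigma <- stats::runif(3, 2.5, 5.0)
      peak <- stats::runif(1, spec@tumorIntensity[1], spec@tumorIntensity[2])
      tc <- .tumorComponent(sh, centre, sigma, peak)
      inCuboid <- tc$component[tc$cuboid["lo", 1]:tc$cuboid["hi", 1],
                               tc$cuboid["lo", 2]:tc$cuboid["hi", 2],
                               tc$cuboid["lo", 3]:tc$cuboid["hi", 3]]
      thr <- 0.4 * max(inCuboid)
      gt <- array(0L, sh)
      gt[tc$component >= thr & tc$component > 0] <- 1L
      vol <- vol + tc$component
      if (spec@noiseSigma > 0)
        vol <- vol + stats::rnorm(length(vol), sd = spec@noiseSigma)
      vol <- pmax(vol, 0)
      dim(vol) <- sh
      prior <- priorPoint(pmin(pmax(round(centre), 1), sh))
      tumorVolumes[i] <- sum(gt) * prod(spec@spacing)
      patients[[i]] <- new("PhantomPatient",
        id = sprintf("P%03d", i),
        volume = petVolume(vol, spec@spacing),
        classLabel = as.integer(classLabel),
        prior = prior,
        gtMask = tumorMask3D(gt, provenance = list(
          rule = "40% of max of noise-free tumour component in bounding cuboid",
          centre = centre, sigma = sigma, peak = peak,
          cuboid = tc$cuboid, threshold = thr)),
        outcome = NA_integer_)
    }
    if (spec@outcomeRule == "volume_median") {
      med <- stats::median(tumorVolumes)
      out <- as.integer(tumorVolumes > med)
      flips <- stats::runif(spec@nPatients) < spec@outcomeFlipProb
      out[flips] <- 1L - out[flips]
      for (i in seq_len(spec@nPatients)) patients[[i]]@outcome <- out[i]
    }
    patients
  })
}

#' Write a cohort to disk as NIfTI + manifest
#'
#' Writes one NIfTI volume and one NIfTI mask per patient plus a CSV
#' manifest with columns `id, class, outcome, px, py, pz` (1-based voxel
#' indices of the prior point). Arrays round-trip exactly through
#' [readCohort()].
#'
#' @param patients list of [PhantomPatient-class].
#' @param dir output directory (created if absent).
#' @return invisibly, a data.frame manifest with file paths appended.
#' @export
writeCohort <- function(patients, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  rows <- lapply(patients, function(p) {
    vf <- file.path(dir, paste0(p@id, "_pet.nii.gz"))
    mf <- file.path(dir, paste0(p@id, "_mask.nii.gz"))
    img <- RNifti::asNifti(p@volume@data)
    img <- RNifti::`pixdim<-`(img, p@volume@spacing)
    RNifti::writeNifti(img, vf)
    msk <- RNifti::asNifti(p@gtMask@data)
    msk <- RNifti::`pixdim<-`(msk, p@volume@spacing)
    RNifti::writeNifti(msk, mf)
    data.frame(id = p@id, class = p@classLabel, outcome = p@outcome,
               px = p@prior@voxel[1], py = p@prior@voxel[2], pz = p@prior@voxel[3],
               volume_file = basename(vf), mask_file = basename(mf))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing `manifest.csv` and the NIfTI files.
#' @return list of [PhantomPatient-class].
#' @export
readCohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    img <- RNifti::readNifti(file.path(dir, row$volume_file))
    msk <- RNifti::readNifti(file.path(dir, row$mask_file))
    sp <- RNifti::pixdim(img)
    new("PhantomPatient",
        id = row$id,
        volume = petVolume(array(as.vector(img), dim = dim(img)), sp),
        classLabel = as.integer(row$class),
        prior = priorPoint(c(row$px, row$py, row$pz)),
        gtMask = tumorMask3D(array(as.vector(msk) >= 0.5, dim = dim(msk)),
                             provenance = list(source = row$mask_file)),
        outcome = as.integer(row$outcome))
  })
}
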