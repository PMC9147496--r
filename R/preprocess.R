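#' Resample a PET volume to isotropic voxels
#'
#' Separable cubic-convolution (bicubic) resampling of the intensity grid
#' to `targetMm` isotropic spacing, the standard spatial normalization for
#' multi-scanner PET. Output voxel `i` (1-based) samples the input at
#' physical coordinate `(i-1) * targetMm` along each axis; edges are
#' clamped. The output has `ceiling(extent / targetMm)` voxels per axis and
#' intensities are clipped at 0 (the cubic kernel can undershoot).
#'
#' @param volume a [PetVolume-class].
#' @param targetMm target isotropic voxel size in mm (default 2).
#' @return a [PetVolume-class] at `targetMm` spacing.
#' @examples
#' v <- petVolume(array(runif(16^3), c(16, 16, 16)), spacing = c(4, 4, 2))
#' dim(volumeData(resampleIsotropic(v, 2)))
#' @export
resampleIsotropic <- function(volume, targetMm = 2) {
  stopifnot(is(volume, "PetVolume"))
  if (!is.finite(targetMm) || targetMm <= 0)
    stop("targetMm must be a positive number")
  n <- dim(volume@data)
  nout <- as.integer(ceiling(n * volume@spacing / targetMm))
  ratio <- targetMm / volume@spacing
  out <- .resample3dCubic(volume@data, nout, ratio)
  petVolume(pmax(out, 0), rep(targetMm, 3))
}

#' Resample a binary mask with nearest-neighbour interpolation
#'
#' Nearest-neighbour keeps the mask binary; used when ground-truth masks
#' must follow a volume through [resampleIsotropic()].
#'
#' @param mask a [TumorMask3D-class].
#' @param spacing current voxel spacing of the mask (mm, length 3).
#' @param targetMm target isotropic spacing.
#' @return a [TumorMask3D-class].
#' @export
resampleMask <- function(mask, spacing, targetMm = 2) {
  stopifnot(is(mask, "TumorMask3D"))
  n <- dim(mask@data)
  nout <- as.integer(ceiling(n * spacing / targetMm))
  ratio <- targetMm / spacing
  out <- .resample3dNearest(mask@data + 0, nout, ratio)
  tumorMask3D(out >= 0.5, provenance = c(mask@provenance,
                                         list(resampled_to_mm = targetMm)))
}

#' SUV normalization to the unit interval
#'
#' Clips intensities to the SUV window `[0, 30]` and divides by 30, the
#' fixed normalization applied before any network sees the data. The
#' output is tagged, and an already-normalized volume passes through
#' unchanged, so the operation is idempotent.
#'
#' @param volume a [PetVolume-class] in SUV units (nonnegative).
#' @return a [PetVolume-class] with values in `[0, 1]`.
#' @examples
#' v <- petVolume(array(c(0, 15, 30, 45), c(4, 1, 1)))
#' volumeData(normalizeSuv(v))
#' @export
normalizeSuv <- function(volume) {
  stopifnot(is(volume, "PetVolume"))
  if (.isNormalized(volume)) return(volume)
  out <- pmin(pmax(volume@data, 0), 30) / 30
  v <- petVolume(out, volume@spacing)
  attr(v@data, "suv_normalized") <- TRUE
  v
}

.isNormalized <- function(volume) isTRUE(attr(volume@data, "suv_normalized"))

#' Maximum intensity projection of a volume
#'
#' Collapses one axis of the volume by taking the voxel-wise maximum.
#' The coronal view collapses the anterior--posterior axis `y` and retains
#' `(z rows, x cols)`; the sagittal view collapses the left--right axis `x`
#' and retains `(z rows, y cols)`. Row index increases with `z` in array
#' order.
#'
#' @param volume a [PetVolume-class].
#' @param view `"coronal"` or `"sagittal"`.
#' @return a [MipImage-class].
#' @examples
#' v <- petVolume(array(runif(4 * 5 * 6), c(4, 5, 6)))
#' dim(mipData(computeMip(v, "coronal")))   # 6 x 4
#' dim(mipData(computeMip(v, "sagittal")))  # 6 x 5
#' @export
computeMip <- function(volume, view = c("coronal", "sagittal")) {
  stopifnot(is(volume, "PetVolume"))
  view <- match.arg(view)
  m <- if (view == "coronal") {
    t(apply(volume@data, c(1, 3), max))   # (z, x)
  } else {
    t(apply(volume@data, c(2, 3), max))   # (z, y)
  }
  new("MipImage", data = m, view = view)
}

#' Project the 3D prior point into a MIP view
#'
#' Drops the view's collapsed axis: coronal gives `(row = z, col = x)`,
#' sagittal `(row = z, col = y)`, matching the [MipImage-class] pixel
#' convention. The two projections back-intersect at the original voxel.
#'
#' @param prior a [PriorPoint-class] (or length-3 voxel index).
#' @param view `"coronal"` or `"sagittal"`.
#' @param volumeShape optional voxel counts for a bounds check.
#' @return numeric(2) `(row, col)` pixel coordinate, 1-based.
#' @examples
#' projectPrior(priorPoint(c(3, 5, 7)), "coronal")   # (7, 3)
#' projectPrior(priorPoint(c(3, 5, 7)), "sagittal")  # (7, 5)
#' @export
projectPrior <- function(prior, view = c("coronal", "sagittal"),
                         volumeShape = NULL) {
  view <- match.arg(view)
  p <- if (is(prior, "PriorPoint")) prior@voxel else as.integer(round(prior))
  if (length(p) != 3L || any(p < 1L)) stop("prior must be a 1-based (x, y, z) voxel")
  if (!is.null(volumeShape) && any(p > volumeShape))
    stop("prior point (", paste(p, collapse = ","), ") outside volume bounds (",
         paste(volumeShape, collapse = ","), ")")
  if (view == "coronal") c(row = p[3], col = p[1]) else c(row = p[3], col = p[2])
}
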