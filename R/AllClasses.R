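#' @useDynLib petcam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' PetVolume: a 3D PET image in SUV-like units
#'
#' The central 3D container. The voxel array is indexed `(x, y, z)` with
#' `x` = left--right, `y` = anterior--posterior and `z` =
#' inferior--superior, 1-based as usual in R. Intensities are nonnegative
#' standardized-uptake-value (SUV) scaled numbers, or values in `[0, 1]`
#' after [normalizeSuv()].
#'
#' @slot data 3D numeric array, dimension `(nx, ny, nz)`.
#' @slot spacing numeric(3), voxel edge length in mm per axis.
#' @export
setClass("PetVolume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    if (length(object@spacing) != 3L) return("spacing must have length 3")
    if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
      return("spacing must be positive and finite")
    if (any(object@data < 0, na.rm = TRUE)) return("data must be nonnegative")
    TRUE
  }
)

#' Construct a PetVolume
#'
#' @param data 3D nonnegative numeric array `(x, y, z)`.
#' @param spacing voxel size in mm, recycled to length 3.
#' @return A [PetVolume-class] object.
#' @examples
#' v <- petVolume(array(1, c(4, 4, 4)), spacing = 2)
#' dim(volumeData(v))
#' @export
petVolume <- function(data, spacing = c(2, 2, 2)) {
  new("PetVolume", data = data, spacing = rep(as.numeric(spacing), length.out = 3L))
}

#' MipImage: a maximum intensity projection of a PetVolume
#'
#' A 2D image whose every pixel is the maximum voxel value along one
#' collapsed axis of the source volume. The row axis is always `z`
#' (increasing with array index); the column axis is `x` for the coronal
#' view (which collapses `y`) and `y` for the sagittal view (which
#' collapses `x`).
#'
#' @slot data numeric matrix `(nz, nx)` for coronal, `(nz, ny)` for sagittal.
#' @slot view `"coronal"` or `"sagittal"`.
#' @export
setClass("MipImage",
  representation(data = "matrix", view = "character"),
  validity = function(object) {
    if (!object@view %in% c("coronal", "sagittal"))
      return("view must be 'coronal' or 'sagittal'")
    if (any(!is.finite(object@data))) return("data must be finite")
    TRUE
  }
)

#' PriorPoint: the single annotated tumour-centre voxel
#'
#' The only localization supervision the method uses: one voxel
#' coordinate at (approximately) the tumour centre, 1-based `(x, y, z)`.
#'
#' @slot voxel integer(3), 1-based voxel index.
#' @export
setClass("PriorPoint",
  representation(voxel = "integer"),
  validity = function(object) {
    if (length(object@voxel) != 3L) return("voxel must have length 3")
    if (any(object@voxel < 1L)) return("voxel indices are 1-based and must be >= 1")
    TRUE
  }
)

#' @rdname PriorPoint-class
#' @param voxel numeric or integer (x, y, z) voxel index, 1-based.
#' @return A [PriorPoint-class].
#' @export
priorPoint <- function(voxel) new("PriorPoint", voxel = as.integer(round(voxel)))

#' HeatMap: a class activation map aligned to a MIP image
#'
#' Holds both the raw low-resolution class response (one value per cell of
#' the final convolutional feature maps) and its bilinear upsampling to the
#' MIP pixel grid, normalized to `[0, 1]` by the map maximum. Values are
#' nonnegative (post-ReLU).
#'
#' @slot data upsampled map, same shape as the source MIP, in `[0, 1]`.
#' @slot raw low-resolution map, shape `(J, Z)` of the feature maps.
#' @slot view the MIP view this map explains.
#' @slot class `"lung"` or `"esophagus"` -- the class whose evidence is mapped.
#' @slot weights the per-feature-map weights used (averaged influences).
#' @export
setClass("HeatMap",
  representation(data = "matrix", raw = "matrix", view = "character",
                 mapClass = "character", weights = "numeric"),
  validity = function(object) {
    if (any(object@data < 0) || any(object@raw < 0))
      return("heat maps are post-ReLU and must be nonnegative")
    if (!object@mapClass %in% c("lung", "esophagus"))
      return("class must be 'lung' or 'esophagus'")
    TRUE
  }
)

#' TumorMask3D: a binary voxel mask
#'
#' @slot data 3D array of 0/1, same shape as its source [PetVolume-class].
#' @slot provenance list recording how the mask was produced (thresholds,
#'   views, refinement).
#' @export
setClass("TumorMask3D",
  representation(data = "array", provenance = "list"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    if (!all(object@data %in% c(0, 1))) return("mask must be binary")
    TRUE
  }
)

#' @rdname TumorMask3D-class
#' @param data 3D binary array.
#' @param provenance optional list of provenance notes.
#' @return A [TumorMask3D-class].
#' @export
tumorMask3D <- function(data, provenance = list()) {
  storage.mode(data) <- "integer"
  new("TumorMask3D", data = data, provenance = provenance)
}

#' PhantomSpec: parameters of the synthetic PET cohort generator
#'
#' See [phantomSpec()] for the constructor and defaults.
#'
#' @slot volumeShape integer(3) voxel counts (x, y, z).
#' @slot spacing numeric(3) voxel size in mm.
#' @slot nPatients integer cohort size.
#' @slot classBalance fraction of lung-cancer patients.
#' @slot tumorIntensity numeric(2) SUV range of tumour peak uptake.
#' @slot decoyIntensity numeric(2) SUV range of physiological decoy uptake.
#' @slot backgroundIntensity scalar SUV of the body envelope.
#' @slot noiseSigma additive Gaussian noise scale (SUV).
#' @slot outcomeRule name of the rule mapping a tumour property to outcome.
#' @slot outcomeFlipProb label-flip probability applied to outcomes.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(volumeShape = "integer", spacing = "numeric",
                 nPatients = "integer", classBalance = "numeric",
                 tumorIntensity = "numeric", decoyIntensity = "numeric",
                 backgroundIntensity = "numeric", noiseSigma = "numeric",
                 outcomeRule = "character", outcomeFlipProb = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (any(object@volumeShape < 16L)) return("volumeShape: all axes must be >= 16 voxels")
    if (any(object@spacing <= 0)) return("spacing: must be positive")
    if (object@nPatients < 1L) return("nPatients: must be positive")
    if (object@classBalance < 0 || object@classBalance > 1)
      return("classBalance: must be in [0, 1]")
    if (diff(object@tumorIntensity) < 0 || any(object@tumorIntensity <= 0))
      return("tumorIntensity: need 0 < min <= max")
    if (diff(object@decoyIntensity) < 0 || any(object@decoyIntensity < 0))
      return("decoyIntensity: need 0 <= min <= max")
    if (object@backgroundIntensity < 0) return("backgroundIntensity: must be >= 0")
    if (object@noiseSigma < 0) return("noiseSigma: must be >= 0")
    if (!object@outcomeRule %in% c("volume_median", "none"))
      return("outcomeRule: must be 'volume_median' or 'none'")
    if (object@outcomeFlipProb < 0 || object@outcomeFlipProb > 0.5)
      return("outcomeFlipProb: must be in [0, 0.5]")
    TRUE
  }
)

#' PhantomPatient: one synthetic patient
#'
#' @slot id patient identifier.
#' @slot volume [PetVolume-class] with noise, SUV scale.
#' @slot classLabel integer, 0 = esophageal, 1 = lung.
#' @slot prior [PriorPoint-class] at the tumour centre.
#' @slot gtMask [TumorMask3D-class] ground truth (40%-of-max threshold of the
#'   noise-free tumour component inside its bounding cuboid).
#' @slot outcome integer 0/1 outcome label, or NA.
#' @export
setClass("PhantomPatient",
  representation(id = "character", volume = "PetVolume", classLabel = "integer",
                 prior = "PriorPoint", gtMask = "TumorMask3D", outcome = "integer"),
  validity = function(object) {
    if (!object@classLabel %in% c(0L, 1L)) return("classLabel must be 0 or 1")
    v <- object@prior@voxel
    if (any(v > dim(object@volume@data))) return("prior point outside volume")
    if (sum(object@gtMask@data) == 0L) return("gt mask must be nonempty")
    if (object@gtMask@data[v[1], v[2], v[3]] != 1L)
      return("prior point must lie inside the ground-truth mask")
    TRUE
  }
)

## ---- accessors ----

#' @describeIn PetVolume-class voxel array accessor
#' @param x object
#' @export
volumeData <- function(x) x@data

#' @describeIn PetVolume-class voxel spacing in mm
#' @export
volumeSpacing <- function(x) x@spacing

#' @describeIn MipImage-class pixel matrix accessor
#' @export
mipData <- function(x) x@data

#' @describeIn MipImage-class view tag ("coronal" or "sagittal")
#' @export
mipView <- function(x) x@view

#' Axis bookkeeping for a MIP view
#'
#' `retainedAxes` gives the 3D axis names that a view's (row, col) map to;
#' `collapsedAxis` the axis the maximum was taken over. Coronal collapses
#' `y` and retains `(z, x)`; sagittal collapses `x` and retains `(z, y)`.
#'
#' @param view `"coronal"` or `"sagittal"`, or a [MipImage-class].
#' @return character vector of axis names.
#' @examples
#' retainedAxes("coronal")
#' collapsedAxis("sagittal")
#' @export
retainedAxes <- function(view) {
  if (is(view, "MipImage")) view <- view@view
  switch(view,
    coronal = c(row = "z", col = "x"),
    sagittal = c(row = "z", col = "y"),
    stop("unknown view: ", view)
  )
}

#' @rdname retainedAxes
#' @export
collapsedAxis <- function(view) {
  if (is(view, "MipImage")) view <- view@view
  switch(view, coronal = "y", sagittal = "x", stop("unknown view: ", view))
}

#' @describeIn HeatMap-class upsampled (MIP-resolution) map accessor
#' @param x object
#' @export
heatmapData <- function(x) x@data

#' @describeIn HeatMap-class raw low-resolution map accessor
#' @export
heatmapRaw <- function(x) x@raw

#' @describeIn TumorMask3D-class binary voxel array accessor
#' @param x object
#' @export
maskData <- function(x) x@data

#' @describeIn PriorPoint-class 1-based (x, y, z) voxel accessor
#' @param x object
#' @export
priorVoxel <- function(x) x@voxel

#' @describeIn PhantomPatient-class the patient's PET volume
#' @param x object
#' @export
patientVolume <- function(x) x@volume

#' @describeIn PhantomPatient-class class label (0 esophageal, 1 lung)
#' @export
patientClass <- function(x) x@classLabel

#' @describeIn PhantomPatient-class prior tumour-centre point
#' @export
patientPrior <- function(x) x@prior

#' @describeIn PhantomPatient-class ground-truth tumour mask
#' @export
patientMask <- function(x) x@gtMask

#' @describeIn PhantomPatient-class binary outcome label (may be NA)
#' @export
patientOutcome <- function(x) x@outcome

## ---- show methods ----

setMethod("show", "PetVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("PetVolume %dx%dx%d voxels, %.3g x %.3g x %.3g mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3],
              min(object@data), max(object@data)))
})

setMethod("show", "MipImage", function(object) {
  d <- dim(object@data)
  ax <- retainedAxes(object@view)
  cat(sprintf("MipImage (%s) %dx%d [rows=%s, cols=%s], max %.3g\n",
              object@view, d[1], d[2], ax["row"], ax["col"], max(object@data)))
})

setMethod("show", "HeatMap", function(object) {
  cat(sprintf("HeatMap (%s view, class %s): raw %dx%d -> %dx%d, mass %.3g\n",
              object@view, object@mapClass, nrow(object@raw), ncol(object@raw),
              nrow(object@data), ncol(object@data), sum(object@data)))
})

setMethod("show", "TumorMask3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("TumorMask3D %dx%dx%d, %d voxels set\n", d[1], d[2], d[3],
              sum(object@data)))
})

setMethod("show", "PhantomPatient", function(object) {
  cat(sprintf("PhantomPatient %s: class %s, outcome %s, tumour %d voxels, prior (%d,%d,%d)\n",
              object@id, if (object@classLabel == 1L) "lung" else "esophageal",
              ifelse(is.na(object@outcome), "NA", object@outcome),
              sum(object@gtMask@data),
              object@prior@voxel[1], object@prior@voxel[2], object@prior@voxel[3]))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %d patients, volume %dx%dx%d @ %.3g mm, ",
                     "lung fraction %.2f, seed %d\n"),
              object@nPatients, object@volumeShape[1], object@volumeShape[2],
              object@volumeShape[3], object@spacing[1], object@classBalance,
              object@seed))
})
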