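#' Binarize a heat map
#'
#' Thresholds at `relThreshold` times the map maximum (mirroring the
#' clinical 40%-of-SUVmax convention) and optionally keeps only the largest
#' connected component, which suppresses residual decoy activations.
#'
#' @param heatmap a [HeatMap-class] or nonnegative matrix.
#' @param relThreshold relative threshold in (0, 1), default 0.4.
#' @param largestComponent keep only the largest 4-connected component.
#' @return binary matrix (0/1 integer) of the heat-map shape.
#' @export
binarizeHeatmap <- function(heatmap, relThreshold = 0.4,
                            largestComponent = TRUE) {
  h <- if (is(heatmap, "HeatMap")) heatmap@data else heatmap
  if (relThreshold <= 0 || relThreshold >= 1)
    stop("relThreshold must be strictly between 0 and 1")
  mx <- max(h)
  if (mx <= 0) {
    warning("all-zero heat map; returning an empty mask")
    return(matrix(0L, nrow(h), ncol(h)))
  }
  m <- matrix(as.integer(h >= relThreshold * mx), nrow(h), ncol(h))
  if (largestComponent && sum(m) > 0) {
    lab <- EBImage::bwlabel(m)
    counts <- tabulate(lab[lab > 0])
    m <- matrix(as.integer(lab == which.max(counts)), nrow(h), ncol(h))
  }
  m
}

#' Reconstruct a 3D mask from two orthogonal 2D masks
#'
#' Back-projects each 2D mask along its collapsed axis and intersects the
#' two prisms: voxel `(x, y, z)` is set iff the coronal mask has `(z, x)`
#' set and the sagittal mask has `(z, y)` set. For an axis-aligned cuboid
#' whose true projections are used as masks the reconstruction is exact;
#' for any shape whose projections are contained in the 2D masks, the
#' reconstruction contains the shape (it is conservative).
#'
#' @param maskCor binary coronal mask `(nz, nx)`.
#' @param maskSag binary sagittal mask `(nz, ny)`.
#' @param volumeShape integer(3) voxel counts (x, y, z).
#' @return a [TumorMask3D-class].
#' @export
reconstruct3d <- function(maskCor, maskSag, volumeShape) {
  nx <- volumeShape[1]; ny <- volumeShape[2]; nz <- volumeShape[3]
  if (!all(dim(maskCor) == c(nz, nx)))
    stop(sprintf("coronal mask is %dx%d; expected (nz, nx) = %dx%d",
                 nrow(maskCor), ncol(maskCor), nz, nx))
  if (!all(dim(maskSag) == c(nz, ny)))
    stop(sprintf("sagittal mask is %dx%d; expected (nz, ny) = %dx%d",
                 nrow(maskSag), ncol(maskSag), nz, ny))
  out <- array(0L, volumeShape)
  for (z in seq_len(nz)) {
    if (any(maskCor[z, ] > 0) && any(maskSag[z, ] > 0))
      out[, , z] <- as.integer(outer(maskCor[z, ] > 0, maskSag[z, ] > 0))
  }
  tumorMask3D(out, provenance = list(method = "back-projection intersection"))
}

#' Refine a mask by the 40%-of-SUVmax rule
#'
#' Keeps the voxels inside the mask whose intensity is at least `frac`
#' times the maximum intensity inside the mask -- the clinical
#' metabolic-tumour-volume protocol applied within the reconstructed
#' region. Idempotent: the maximum inside the refined mask is unchanged.
#'
#' @param mask a [TumorMask3D-class].
#' @param volume the [PetVolume-class] the mask lives in.
#' @param frac relative intensity threshold (default 0.4).
#' @return a [TumorMask3D-class].
#' @export
refineBySuv <- function(mask, volume, frac = 0.4) {
  stopifnot(is(mask, "TumorMask3D"), is(volume, "PetVolume"))
  if (sum(mask@data) == 0L) {
    warning("empty mask; returned unchanged")
    return(mask)
  }
  v <- volume@data
  mx <- max(v[mask@data == 1L])
  keep <- mask@data == 1L & v >= frac * mx
  tumorMask3D(array(as.integer(keep), dim(v)),
              provenance = c(mask@provenance, list(suv_refine_frac = frac)))
}

#' Segment a tumour in a PET volume from its two MIP heat maps
#'
#' The full weakly supervised inference path: SUV normalization, coronal
#' and sagittal MIPs, class prediction (or a supplied class), class
#' activation maps for both views, relative thresholding with
#' largest-component cleanup, back-projection intersection, and (optional)
#' 40%-of-SUVmax refinement inside the reconstructed prism.
#'
#' @param model a trained [MipClassifier-class].
#' @param volume a [PetVolume-class].
#' @param relThreshold heat-map binarization threshold (default 0.4).
#' @param refine apply [refineBySuv()] inside the reconstruction
#'   (default `FALSE`; the cross-validation harness enables it).
#' @param class force the CAM class; `NULL` uses the predicted class.
#' @return list: `mask` ([TumorMask3D-class]), `class`, `prob`,
#'   `heatmaps` (named list of [HeatMap-class]).
#' @export
segmentVolume <- function(model, volume, relThreshold = 0.4, refine = FALSE,
                          class = NULL) {
  nv <- normalizeSuv(volume)
  cls <- classifyPatient(model, volume)
  useClass <- class %||% cls$class
  heatmaps <- list()
  masks2d <- list()
  for (i in seq_along(c("coronal", "sagittal"))) {
    v <- c("coronal", "sagittal")[i]
    hm <- computeCam(model, computeMip(nv, v), class = useClass,
                     prediction = cls$predictions[[i]])
    heatmaps[[v]] <- hm
    masks2d[[v]] <- suppressWarnings(binarizeHeatmap(hm, relThreshold))
  }
  mask <- reconstruct3d(masks2d$coronal, masks2d$sagittal, dim(volume@data))
  if (refine && sum(mask@data) > 0) mask <- refineBySuv(mask, volume)
  mask@provenance$relThreshold <- relThreshold
  mask@provenance$class <- useClass
  list(mask = mask, class = cls$class, prob = cls$prob, heatmaps = heatmaps)
}
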