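#' CAM weights: averaged feature influences
#'
#' One weight per feature map: the mean over the `J x Z` spatial positions
#' of that map's influence on the class score.
#'
#' @param influence array `(J, Z, D)` from [featureInfluence()].
#' @return numeric(D) weights.
#' @examples
#' infl <- array(1:8 / 8, c(2, 2, 2))
#' camWeights(infl)  # per-map spatial means
#' @export
camWeights <- function(influence) {
  if (length(dim(influence)) != 3L)
    stop("influence must be a (J, Z, D) array")
  apply(influence, 3, mean)
}

#' Pre-heat map: weighted sum of feature maps
#'
#' Elementwise sum over maps of `w_i * f_i`.
#'
#' @param features array `(J, Z, D)`.
#' @param w numeric(D) CAM weights.
#' @return `J x Z` matrix (may contain negative values).
#' @export
preHeatmap <- function(features, w) {
  d <- dim(features)
  if (length(d) != 3L) stop("features must be a (J, Z, D) array")
  if (length(w) != d[3])
    stop("got ", length(w), " weights for ", d[3], " feature maps")
  matrix(matrix(features, ncol = d[3]) %*% w, d[1], d[2])
}

#' Rectify a pre-heat map
#'
#' Keeps only the positively contributing evidence: elementwise
#' `max(0, x)`.
#'
#' @param pre `J x Z` matrix.
#' @return nonnegative `J x Z` matrix.
#' @export
reluHeatmap <- function(pre) pmax(pre, 0)

#' Upsample a raw heat map to MIP resolution
#'
#' Corner-aligned bilinear interpolation from the coarse `J x Z` class
#' response grid to the MIP pixel grid. Bilinear interpolation of a
#' nonnegative map is nonnegative and preserves the location of the
#' maximum to within one raw-cell footprint.
#'
#' @param raw nonnegative `J x Z` matrix.
#' @param targetShape integer(2) output `(rows, cols)`; must not be smaller
#'   than the raw map.
#' @return matrix of size `targetShape`.
#' @export
upsampleHeatmap <- function(raw, targetShape) {
  if (any(targetShape < dim(raw)))
    stop("target shape must not be smaller than the raw map")
  A <- .interpMatrix(nrow(raw), targetShape[1])
  B <- .interpMatrix(ncol(raw), targetShape[2])
  pmax(A %*% raw %*% t(B), 0)
}

#' Generate the class activation heat map for one MIP view
#'
#' The full CAM pipeline: influence of every feature-map element on the
#' class score, per-map averaged weights, weighted feature-map sum, ReLU,
#' bilinear upsampling to the MIP grid, and normalization to `[0, 1]` by
#' the map maximum (when positive). The normalization makes downstream
#' thresholds and the distance constraint scale-free.
#'
#' @param model a [MipClassifier-class].
#' @param mip a [MipImage-class].
#' @param class `"lung"`, `"esophagus"`, or `NULL` to use the class the
#'   network itself predicts for this view.
#' @param prediction optional precomputed [classifierForward()] result.
#' @return a [HeatMap-class].
#' @export
computeCam <- function(model, mip, class = NULL, prediction = NULL) {
  stopifnot(is(mip, "MipImage"))
  if (is.null(prediction)) prediction <- classifierForward(model, mip)
  if (is.null(class))
    class <- if (prediction$yhat >= 0.5) "lung" else "esophagus"
  infl <- featureInfluence(model, prediction, class, wrt = "logit")
  w <- camWeights(infl)
  raw <- reluHeatmap(preHeatmap(prediction$features, w))
  up <- upsampleHeatmap(raw, dim(mip@data))
  mx <- max(up)
  if (mx > 0) up <- up / mx
  new("HeatMap", data = up, raw = raw, view = mip@view, mapClass = class,
      weights = w)
}
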