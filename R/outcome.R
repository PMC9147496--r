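#' Configuration of the 3D outcome network
#'
#' A small 3D CNN for treatment-outcome prediction from the segmented
#' tumour: two 3D convolutional layers (3^3 kernels) each followed by
#' 2^3 max pooling, then a dense hidden layer and a single sigmoid unit.
#' The default takes 48^3 crops with 32 and 64 channels;
#' [compactOutcomeConfig()] is the scaled variant for the default phantom.
#'
#' @param cropShape integer(3) input patch size in voxels.
#' @param channels integer(2) channels of the two conv layers.
#' @param denseWidth width of the dense hidden layer.
#' @param dropout dropout rate on the dense hidden layer.
#' @return a config list with the derived flattened feature length.
#' @export
outcomeConfig <- function(cropShape = c(48, 48, 48), channels = c(32, 64),
                          denseWidth = 128, dropout = 0.5) {
  n <- as.integer(cropShape)
  for (i in 1:2) n <- n %/% 2L   # conv is 'same'; each pool halves
  list(cropShape = as.integer(cropShape), channels = as.integer(channels),
       denseWidth = as.integer(denseWidth), dropout = dropout,
       flatLen = prod(n) * channels[2])
}

#' @rdname outcomeConfig
#' @export
compactOutcomeConfig <- function() {
  outcomeConfig(cropShape = c(24, 24, 24), channels = c(16, 32),
                denseWidth = 64)
}

#' OutcomeNet: the 3D radiomics outcome classifier
#'
#' @slot params named list of parameter arrays.
#' @slot config an [outcomeConfig()] list.
#' @export
setClass("OutcomeNet", representation(params = "list", config = "list"))

setMethod("show", "OutcomeNet", function(object) {
  cfg <- object@config
  cat(sprintf("OutcomeNet: %dx%dx%d crops, conv %d/%d + dense %d, %d parameters\n",
              cfg$cropShape[1], cfg$cropShape[2], cfg$cropShape[3],
              cfg$channels[1], cfg$channels[2], cfg$denseWidth,
              sum(vapply(object@params, length, 1L))))
})

#' Initialize the outcome network
#'
#' @param config an [outcomeConfig()] list.
#' @param seed optional integer seed.
#' @return an [OutcomeNet-class].
#' @export
outcomeNet <- function(config = outcomeConfig(), seed = NULL) {
  .withSeed(seed, function() {
    p <- list(
      cW1 = .heInit(c(3, 3, 3, 1, config$channels[1]), 27),
      cb1 = numeric(config$channels[1]),
      cW2 = .heInit(c(3, 3, 3, config$channels[1], config$channels[2]),
                    27 * config$channels[1]),
      cb2 = numeric(config$channels[2]),
      dW1 = .heInit(c(config$denseWidth, config$flatLen), config$flatLen),
      db1 = numeric(config$denseWidth),
      dW2 = .heInit(c(1, config$denseWidth), config$denseWidth),
      db2 = 0
    )
    new("OutcomeNet", params = p, config = config)
  })
}

#' Crop a fixed-size tumour patch from a volume
#'
#' Extracts a patch of `cropShape` voxels centred on the mask centroid,
#' zero-padding where the patch extends beyond the volume. Intended to run
#' on SUV-normalized volumes so intensities are in `[0, 1]`.
#'
#' @param volume a [PetVolume-class].
#' @param mask a nonempty [TumorMask3D-class].
#' @param cropShape integer(3) patch size.
#' @param maskOnly zero intensities outside the mask (default `FALSE`:
#'   the patch keeps tumour plus margin).
#' @return 3D array of `cropShape` with attribute `centroid`.
#' @export
cropTumor <- function(volume, mask, cropShape = c(48, 48, 48),
                      maskOnly = FALSE) {
  stopifnot(is(volume, "PetVolume"), is(mask, "TumorMask3D"))
  if (sum(mask@data) == 0L)
    stop("empty mask: run segmentation (segmentVolume) before cropping")
  v <- volume@data
  if (maskOnly) v <- v * mask@data
  idx <- which(mask@data == 1L, arr.ind = TRUE)
  centroid <- round(colMeans(idx))
  out <- array(0, cropShape)
  lo <- centroid - (cropShape %/% 2L)       # 1-based start minus one
  srcLo <- pmax(lo + 1L, 1L)
  srcHi <- pmin(lo + cropShape, dim(v))
  dstLo <- srcLo - lo
  dstHi <- dstLo + (srcHi - srcLo)
  out[dstLo[1]:dstHi[1], dstLo[2]:dstHi[2], dstLo[3]:dstHi[3]] <-
    v[srcLo[1]:srcHi[1], srcLo[2]:srcHi[2], srcLo[3]:srcHi[3]]
  attr(out, "centroid") <- centroid
  out
}

# Forward with cache; crop is (X, Y, Z) array.
.outcomeForwardFull <- function(model, crop, train = FALSE) {
  p <- model@params
  cfg <- model@config
  drop <- cfg$dropout
  x <- array(crop, c(dim(crop), 1L))
  z1 <- .conv3dForward(x, p$cW1, p$cb1, 1L, 1L)
  a1 <- z1; a1[a1 < 0] <- 0
  pl1 <- .maxpool3dForward(a1)
  z2 <- .conv3dForward(pl1$out, p$cW2, p$cb2, 1L, 1L)
  a2 <- z2; a2[a2 < 0] <- 0
  pl2 <- .maxpool3dForward(a2)
  V <- as.vector(pl2$out)
  zd <- as.vector(p$dW1 %*% V) + p$db1
  h <- .elu(zd)
  m1 <- NULL
  if (train && drop > 0) {
    m1 <- stats::runif(length(h)) >= drop
    h <- h * m1 / (1 - drop)
  }
  logit <- as.vector(p$dW2 %*% h) + p$db2
  list(yhat = .sigmoid(logit), logit = logit,
       cache = list(x = x, z1 = z1, a1 = a1, pl1 = pl1, z2 = z2, a2 = a2,
                    pl2 = pl2, V = V, zd = zd, h = h, m1 = m1, train = train))
}

#' Outcome probability for one tumour crop
#'
#' @param model an [OutcomeNet-class].
#' @param crop 3D array matching the configured crop shape.
#' @return probability in (0, 1); deterministic (dropout off).
#' @export
outcomeForward <- function(model, crop) {
  stopifnot(is(model, "OutcomeNet"))
  if (!all(dim(crop) == model@config$cropShape))
    stop(sprintf("crop is %s but the network expects %s",
                 paste(dim(crop), collapse = "x"),
                 paste(model@config$cropShape, collapse = "x")))
  .outcomeForwardFull(model, crop)$yhat
}

.outcomeBackward <- function(model, cache, dlogit) {
  p <- model@params
  drop <- model@config$dropout
  g <- list()
  g$dW2 <- dlogit * matrix(cache$h, nrow = 1)
  g$db2 <- dlogit
  gh <- as.vector(t(p$dW2)) * dlogit
  if (cache$train && !is.null(cache$m1)) gh <- gh * cache$m1 / (1 - drop)
  gzd <- gh * .eluGrad(cache$zd)
  g$dW1 <- gzd %o% cache$V
  g$db1 <- gzd
  gV <- as.vector(t(p$dW1) %*% gzd)
  gp2 <- array(gV, dim = dim(cache$pl2$out))
  ga2 <- .maxpool3dBackward(gp2, cache$pl2$idx, dim(cache$a2))
  gz2 <- ga2 * (cache$z2 > 0)
  bw2 <- .conv3dBackward(cache$pl1$out, p$cW2, gz2, 1L, 1L)
  g$cW2 <- bw2$gw; g$cb2 <- bw2$gb
  ga1 <- .maxpool3dBackward(bw2$gx, cache$pl1$idx, dim(cache$a1))
  gz1 <- ga1 * (cache$z1 > 0)
  bw1 <- .conv3dBackward(cache$x, p$cW1, gz1, 1L, 1L)
  g$cW1 <- bw1$gw; g$cb1 <- bw1$gb
  g
}

#' Train the outcome network
#'
#' Mini-batch Adam training with binary cross-entropy on fixed-size tumour
#' crops. The same routine trains on physician (ground-truth) masks or on
#' masks predicted by the weakly supervised segmentation -- only the crops
#' differ.
#'
#' @param crops list of 3D arrays from [cropTumor()].
#' @param labels binary outcome labels, one per crop.
#' @param config an [outcomeConfig()] list.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batchSize mini-batch size.
#' @param seed integer seed (initialization, shuffling, dropout).
#' @param verbose print per-epoch loss.
#' @return list: `model` ([OutcomeNet-class]) and `history` (per-epoch loss).
#' @export
trainOutcome <- function(crops, labels, config = outcomeConfig(),
                         epochs = 50, lr = 1e-3, batchSize = 8, seed = NULL,
                         verbose = FALSE) {
  labels <- as.numeric(labels)
  if (length(crops) != length(labels)) stop("one label per crop required")
  if (length(unique(labels[!is.na(labels)])) < 2L)
    stop("outcome training needs both classes present")
  .withSeed(seed, function() {
    model <- outcomeNet(config)
    optState <- .adamInit(model@params)
    hist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample(length(crops))
      epLoss <- 0; nb <- 0L
      for (b in split(ord, ceiling(seq_along(ord) / batchSize))) {
        grads <- lapply(model@params, function(p) p * 0)
        bl <- 0
        for (i in b) {
          fw <- .outcomeForwardFull(model, crops[[i]], train = TRUE)
          bl <- bl + classificationLoss(labels[i], fw$yhat)
          dlogit <- (fw$yhat - labels[i]) / length(b)
          g <- .outcomeBackward(model, fw$cache, dlogit)
          for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
        }
        upd <- .adamUpdate(model@params, grads, optState, lr)
        model@params <- upd$params
        optState <- upd$state
        epLoss <- epLoss + bl / length(b)
        nb <- nb + 1L
      }
      hist[ep] <- epLoss / nb
      if (verbose) message(sprintf("epoch %3d  loss %.4f", ep, hist[ep]))
    }
    list(model = model, history = data.frame(epoch = seq_len(epochs),
                                             loss = hist))
  })
}

#' Predict outcomes for a set of crops
#'
#' @param model an [OutcomeNet-class].
#' @param crops list of 3D arrays.
#' @return numeric vector of probabilities.
#' @export
predictOutcome <- function(model, crops) {
  vapply(crops, function(cr) outcomeForward(model, cr), 0)
}
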