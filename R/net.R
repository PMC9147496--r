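#' Configuration of the MIP classifier
#'
#' An eight-layer convolutional feature extractor (3x3 kernels, ReLU,
#' stride-2 downsampling at selected layers) followed by a dense head of
#' 128 and 64 elu units with dropout 0.5 and a single sigmoid output. The
#' default geometry maps a 416 x 160 MIP to 13 x 5 feature maps of depth
#' 128 (a 1/32 stride plan); [compactClassifierConfig()] is the scaled
#' variant used with the default phantom. Both views (coronal, sagittal)
#' share one network.
#'
#' @param inputShape MIP size `(rows, cols)` the network expects.
#' @param channels output channels per conv layer.
#' @param strides stride per conv layer (1 or 2); the product is the total
#'   downsampling factor.
#' @param denseWidths widths of the two hidden dense layers.
#' @param dropout dropout rate on the dense hidden layers during training.
#' @param seedNote all kernels are 3x3 with `same` padding.
#' @return a config list with the derived feature-map shape
#'   `featureShape = (J, Z, D)`.
#' @examples
#' cfg <- classifierConfig()
#' cfg$featureShape   # 13 5 128
#' @export
classifierConfig <- function(inputShape = c(416, 160),
                             channels = c(16, 16, 32, 32, 64, 64, 128, 128),
                             strides = c(2, 2, 1, 2, 1, 2, 1, 2),
                             denseWidths = c(128, 64),
                             dropout = 0.5,
                             seedNote = NULL) {
  if (length(channels) != length(strides))
    stop("channels and strides must have one entry per conv layer")
  n <- inputShape
  for (s in strides) n <- floor((n - 1) / s) + 1  # 3x3 kernel, pad 1
  cfg <- list(inputShape = as.integer(inputShape),
              channels = as.integer(channels),
              strides = as.integer(strides),
              denseWidths = as.integer(denseWidths),
              dropout = dropout,
              featureShape = as.integer(c(n, channels[length(channels)])))
  cfg
}

#' @rdname classifierConfig
#' @param inputShape MIP size for the compact variant.
#' @details The compact variant downsamples by 4 instead of 32, so its
#'   activation-map cells cover 4 x 4 MIP pixels: at phantom scale the
#'   tumour spans several cells, which is what lets the distance
#'   constraint shape a localized map.
#' @export
compactClassifierConfig <- function(inputShape = c(128, 64)) {
  classifierConfig(inputShape = inputShape,
                   channels = c(8, 8, 16, 16, 32, 32, 64, 64),
                   strides = c(2, 1, 2, 1, 1, 1, 1, 1))
}

#' MipClassifier: the shared-weight MIP classification network
#'
#' @slot params named list of parameter arrays (conv kernels `cW*`/`cb*`,
#'   dense weights `dW*`/`db*`).
#' @slot config a [classifierConfig()] list.
#' @export
setClass("MipClassifier", representation(params = "list", config = "list"))

setMethod("show", "MipClassifier", function(object) {
  cfg <- object@config
  cat(sprintf("MipClassifier: input %dx%d -> features %dx%dx%d, %d conv layers, dense %s\n",
              cfg$inputShape[1], cfg$inputShape[2],
              cfg$featureShape[1], cfg$featureShape[2], cfg$featureShape[3],
              length(cfg$channels), paste(cfg$denseWidths, collapse = "/")))
  cat(sprintf("  %d parameters\n", sum(vapply(object@params, length, 1L))))
})

#' Initialize a MIP classifier
#'
#' He-scaled Gaussian initialization, reproducible given `seed`.
#'
#' @param config a [classifierConfig()] list.
#' @param seed optional integer seed for the initialization draw.
#' @return a [MipClassifier-class].
#' @examples
#' net <- mipClassifier(compactClassifierConfig(), seed = 1)
#' net
#' @export
mipClassifier <- function(config = classifierConfig(), seed = NULL) {
  .withSeed(seed, function() {
    params <- list()
    cin <- 1L
    for (l in seq_along(config$channels)) {
      cout <- config$channels[l]
      params[[paste0("cW", l)]] <- .heInit(c(3, 3, cin, cout), 9 * cin)
      params[[paste0("cb", l)]] <- numeric(cout)
      cin <- cout
    }
    K <- prod(config$featureShape)
    # two class logits (esophagus, lung); the reported probability is the
    # sigmoid of their difference
    widths <- c(config$denseWidths, 2L)
    fan <- K
    for (l in seq_along(widths)) {
      params[[paste0("dW", l)]] <- .heInit(c(widths[l], fan), fan)
      params[[paste0("db", l)]] <- numeric(widths[l])
      fan <- widths[l]
    }
    new("MipClassifier", params = params, config = config)
  })
}

# Conv stack forward; x is (H, W, 1). Returns post-ReLU feature maps and a
# cache of layer inputs / pre-activations for the backward pass.
.convForward <- function(model, x) {
  cfg <- model@config
  cache <- vector("list", length(cfg$channels))
  a <- x
  for (l in seq_along(cfg$channels)) {
    z <- .conv2dForward(a, model@params[[paste0("cW", l)]],
                        model@params[[paste0("cb", l)]],
                        cfg$strides[l], 1L)
    cache[[l]] <- list(input = a, pre = z)
    a <- z
    a[a < 0] <- 0
  }
  list(features = a, cache = cache)
}

#' Dense head forward pass from feature maps
#'
#' Flattens the feature-map stack into the vector `V`, applies the two elu
#' dense layers (with inverted dropout when `train = TRUE`) and the output
#' layer with one logit per class (esophagus, lung). The reported class
#' probability is the sigmoid of the logit difference, so the output is a
#' single lung-class probability exactly as with one sigmoid unit, while
#' each class keeps its own activation-map readout. Exposed separately so
#' the influence computation can be checked against finite differences on
#' the head alone.
#'
#' @param model a [MipClassifier-class].
#' @param features array `(J, Z, D)` of last-layer feature maps.
#' @param train logical; apply dropout.
#' @param masks optional precomputed dropout masks (list of 2).
#' @return list with `yhat`, `logits` (esophagus, lung) and a cache for the
#'   backward pass.
#' @export
headForward <- function(model, features, train = FALSE, masks = NULL) {
  p <- model@params
  drop <- model@config$dropout
  V <- as.vector(features)
  z1 <- as.vector(p$dW1 %*% V) + p$db1
  h1 <- .elu(z1)
  m1 <- NULL
  if (train && drop > 0) {
    m1 <- masks[[1]] %||% (stats::runif(length(h1)) >= drop)
    h1 <- h1 * m1 / (1 - drop)
  }
  z2 <- as.vector(p$dW2 %*% h1) + p$db2
  h2 <- .elu(z2)
  m2 <- NULL
  if (train && drop > 0) {
    m2 <- masks[[2]] %||% (stats::runif(length(h2)) >= drop)
    h2 <- h2 * m2 / (1 - drop)
  }
  logits <- as.vector(p$dW3 %*% h2) + p$db3
  yhat <- .sigmoid(logits[2] - logits[1])
  list(yhat = yhat, logits = logits,
       cache = list(V = V, z1 = z1, h1 = h1, z2 = z2, h2 = h2,
                    m1 = m1, m2 = m2, train = train))
}

# Backward through the dense head given d(loss)/d(logits) (length 2).
# Returns gradients for the dense parameters and for the flattened
# feature vector V. With paramGrads = FALSE the large first-layer weight
# gradient is not materialized; the caller assembles it from gz1 and V in
# one batched matrix product.
.headBackward <- function(model, cache, dlogits, paramGrads = TRUE) {
  p <- model@params
  drop <- model@config$dropout
  g <- list()
  gh2 <- as.vector(crossprod(p$dW3, dlogits))
  if (cache$train && !is.null(cache$m2)) gh2 <- gh2 * cache$m2 / (1 - drop)
  gz2 <- gh2 * .eluGrad(cache$z2)
  gh1 <- as.vector(crossprod(p$dW2, gz2))
  if (cache$train && !is.null(cache$m1)) gh1 <- gh1 * cache$m1 / (1 - drop)
  gz1 <- gh1 * .eluGrad(cache$z1)
  g$gz1 <- gz1
  g$gz2 <- gz2
  g$db3 <- dlogits
  g$db2 <- gz2
  g$db1 <- gz1
  g$V <- as.vector(crossprod(p$dW1, gz1))
  if (paramGrads) {
    g$dW3 <- dlogits %o% cache$h2
    g$dW2 <- gz2 %o% cache$h1
    g$dW1 <- gz1 %o% cache$V
  }
  g
}

#' Forward pass of the MIP classifier
#'
#' @param model a [MipClassifier-class].
#' @param mip a [MipImage-class] or numeric matrix matching the configured
#'   input size.
#' @param train logical; enables dropout (training mode). In evaluation
#'   mode the forward pass is deterministic.
#' @return an object of class `petcamPrediction`: list with `yhat` (the
#'   lung-class probability), `logit`, `features` (the post-ReLU last-layer
#'   feature-map stack, `(J, Z, D)`), and internal caches.
#' @examples
#' net <- mipClassifier(compactClassifierConfig(c(32, 16)), seed = 1)
#' pr <- classifierForward(net, matrix(0, 32, 16))
#' pr$yhat
#' dim(pr$features)
#' @export
classifierForward <- function(model, mip, train = FALSE) {
  stopifnot(is(model, "MipClassifier"))
  m <- if (is(mip, "MipImage")) mip@data else mip
  cfg <- model@config
  if (!all(dim(m) == cfg$inputShape))
    stop(sprintf("input is %dx%d but the network expects %dx%d",
                 nrow(m), ncol(m), cfg$inputShape[1], cfg$inputShape[2]))
  x <- array(m, c(dim(m), 1L))
  conv <- .convForward(model, x)
  head <- headForward(model, conv$features, train = train)
  structure(list(yhat = head$yhat, logits = head$logits,
                 features = conv$features,
                 convCache = conv$cache, headCache = head$cache),
            class = "petcamPrediction")
}

#' @export
print.petcamPrediction <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("petcamPrediction: P(lung) = %.4f, features %dx%dx%d\n",
              x$yhat, d[1], d[2], d[3]))
  invisible(x)
}

#' Influence of each feature-map element on the class score
#'
#' The partial derivative of the class score with respect to every element
#' of the last-layer feature maps, computed analytically by
#' backpropagation through the dense head in evaluation mode. For the
#' esophagus class the derivative is negated (the output unit scores the
#' lung class).
#'
#' With `wrt = "probability"` the derivative of the class probability
#' (`yhat` for lung, `1 - yhat` for esophagus) is returned. With
#' `wrt = "logit"` the derivative of that class's own pre-sigmoid score is
#' used instead; the logit form does not vanish when the classifier
#' saturates and is what the CAM construction uses.
#'
#' @param model a [MipClassifier-class].
#' @param prediction a `petcamPrediction` from [classifierForward()].
#' @param class `"lung"` or `"esophagus"`.
#' @param wrt differentiate the `"probability"` (default) or the `"logit"`.
#' @return array `(J, Z, D)` of derivatives.
#' @export
featureInfluence <- function(model, prediction,
                             class = c("lung", "esophagus"),
                             wrt = c("probability", "logit")) {
  class <- match.arg(class)
  wrt <- match.arg(wrt)
  if (is.null(prediction$features)) stop("prediction carries no feature maps")
  head <- if (isTRUE(prediction$headCache$train)) {
    headForward(model, prediction$features, train = FALSE)
  } else {
    list(yhat = prediction$yhat, cache = prediction$headCache)
  }
  dlogits <- if (wrt == "probability") {
    s <- head$yhat * (1 - head$yhat)       # d yhat / d (logit difference)
    if (class == "lung") c(-s, s) else c(s, -s)
  } else {
    if (class == "lung") c(0, 1) else c(1, 0)
  }
  g <- .headBackward(model, head$cache, dlogits)
  array(g$V, dim = dim(prediction$features))
}

# Backward through the conv stack given d(loss)/d(features) (post-ReLU).
# Returns gradients for all conv parameters.
.convBackward <- function(model, cache, gFeatures) {
  cfg <- model@config
  grads <- list()
  g <- gFeatures
  for (l in rev(seq_along(cfg$channels))) {
    g <- g * (cache[[l]]$pre > 0)   # through this layer's ReLU
    bw <- .conv2dBackward(cache[[l]]$input, model@params[[paste0("cW", l)]],
                          g, cfg$strides[l], 1L)
    grads[[paste0("cW", l)]] <- bw$gw
    grads[[paste0("cb", l)]] <- bw$gb
    g <- bw$gx
  }
  grads
}

#' Classify a patient volume from its two MIP views
#'
#' Normalizes the volume, computes the coronal and sagittal MIPs, runs both
#' through the shared network and averages the two class probabilities.
#'
#' @param model a [MipClassifier-class].
#' @param volume a [PetVolume-class].
#' @return list with `prob` (mean lung probability), `class` (`"lung"` or
#'   `"esophagus"`), and the per-view `predictions`.
#' @export
classifyPatient <- function(model, volume) {
  nv <- normalizeSuv(volume)
  preds <- lapply(c("coronal", "sagittal"), function(v)
    classifierForward(model, computeMip(nv, v)))
  prob <- mean(vapply(preds, `[[`, 0, "yhat"))
  list(prob = prob, class = if (prob >= 0.5) "lung" else "esophagus",
       predictions = preds)
}

#' Save / load a model checkpoint
#'
#' Single-file serialized weights + configuration.
#'
#' @param model a [MipClassifier-class] or [OutcomeNet-class].
#' @param path file path.
#' @return `loadModel` returns the model object.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
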