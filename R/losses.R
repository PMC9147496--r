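#' Binary cross-entropy classification loss
#'
#' `-(1/n) sum(y log yhat + (1-y) log(1-yhat))`. Probabilities are clamped
#' to `[1e-7, 1 - 1e-7]` so boundary predictions yield a finite loss.
#'
#' @param y binary labels (1 = lung).
#' @param yhat predicted probabilities, same length.
#' @return nonnegative scalar.
#' @examples
#' classificationLoss(1, 0.5)  # log 2
#' @export
classificationLoss <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have the same length")
  eps <- 1e-7
  yhat <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(yhat) + (1 - y) * log(1 - yhat))
}

#' Distance constraint between a heat map and the prior point
#'
#' The activation-weighted mean Euclidean pixel distance between the heat
#' map and the projected tumour-centre point `p`:
#' `sum_i h(q_i) d(q_i, p) / sum_i h(q_i)` over all heat-map pixels `q_i`.
#' Weighting by the activation is what couples the constraint to the
#' network: moving class evidence closer to the prior point lowers the
#' loss, and the gradient flows through `h`. The value is invariant to
#' rescaling the heat map, so normalized and unnormalized maps give the
#' same loss. An all-zero heat map returns 0 by convention.
#'
#' @param heatmap a [HeatMap-class] or nonnegative matrix.
#' @param p2d `(row, col)` projected prior point, inside the map bounds.
#' @return nonnegative scalar (pixels).
#' @examples
#' h <- matrix(0, 9, 9); h[5, 9] <- 1
#' distanceLoss(h, c(5, 4))  # a point mass 5 pixels away
#' @export
distanceLoss <- function(heatmap, p2d) {
  h <- if (is(heatmap, "HeatMap")) heatmap@data else heatmap
  if (any(h < 0)) stop("heat map must be nonnegative")
  if (p2d[1] < 1 || p2d[1] > nrow(h) || p2d[2] < 1 || p2d[2] > ncol(h))
    stop("prior projection (", p2d[1], ",", p2d[2], ") outside heat map bounds")
  s <- sum(h)
  if (s <= 1e-12) return(0)
  d <- .distMatrix(nrow(h), ncol(h), p2d)
  sum(h * d) / s
}

#' Global multitask loss
#'
#' `loss_glob = L_class + alpha * L_distance`, with `alpha = 1` by default.
#' `alpha = 0` is exactly the classification-only (no prior knowledge)
#' ablation.
#'
#' @param lClass classification loss.
#' @param lDistance distance loss.
#' @param alpha nonnegative weight of the distance constraint.
#' @return scalar.
#' @export
globalLoss <- function(lClass, lDistance, alpha = 1) {
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be a nonnegative number")
  lClass + alpha * lDistance
}

# Cell-centre distance matrix for a view: raw CAM cell (r, c) sits at the
# corner-aligned MIP pixel its bilinear upsampling footprint is centred
# on; distances to the projected prior are in units of the MIP diagonal.
.cellDistMatrix <- function(featureDim, inputShape, p2d) {
  J <- featureDim[1]; Zc <- featureDim[2]
  rows <- if (J > 1) 1 + (seq_len(J) - 1) * (inputShape[1] - 1) / (J - 1) else
    (1 + inputShape[1]) / 2
  cols <- if (Zc > 1) 1 + (seq_len(Zc) - 1) * (inputShape[2] - 1) / (Zc - 1) else
    (1 + inputShape[2]) / 2
  sqrt(outer((rows - p2d[1])^2, (cols - p2d[2])^2, `+`)) /
    sqrt(sum(inputShape^2))
}

# Per-view distance objective and its gradient w.r.t. the feature maps,
# with the CAM weights w treated as stop-gradient constants.
#
# The training objective weights cell distances by a softmax spatial
# attention over the pre-heat map (scale-normalized, temperature Temp)
# instead of the raw rectified activations: the attention mass is always
# exactly 1, so the objective has no all-zero degenerate optimum, its
# gradient is bounded and nonzero everywhere (rectified-away cells can be
# revived), and it shrinks automatically as the map's scale grows. Its
# minimum -- all attention at the cell containing the prior point --
# coincides with the rectified CAM peaking at the prior, which is what
# inference thresholds.
.distanceGradView <- function(features, w, p2d, dm, Temp = 0.1) {
  d <- dim(features)
  pre <- preHeatmap(features, w)
  sc <- 1 / (max(abs(pre)) + 1e-8)   # scale held constant in the backward
  z <- pre * (sc / Temp)
  a <- exp(z - max(z))
  a <- a / sum(a)
  loss <- sum(a * dm)
  gpre <- (sc / Temp) * a * (dm - loss)
  gF <- array(as.vector(gpre) %o% w, d)
  # sensitivity of the loss to the CAM weights themselves (features frozen)
  gw <- as.vector(crossprod(matrix(features, ncol = d[3]), as.vector(gpre)))
  list(loss = loss, gF = gF, gw = gw)
}

# Gradient of the distance loss w.r.t. the dense-head weights through the
# CAM weights w_i = mean_jz d(logit_C)/d(f_i^{jz}). The elu-derivative
# factors are evaluated at the current activations and treated as
# constants (unrolled first-order treatment); bias paths vanish. This is
# the pathway that lets the head develop class-specific positive evidence
# where the constraint needs it.
.distanceHeadGrads <- function(model, evalCache, gw, featureDim, classIdx) {
  p <- model@params
  D1 <- .eluGrad(evalCache$z1)
  D2 <- .eluGrad(evalCache$z2)
  N <- featureDim[1] * featureDim[2]
  # dL/dI at each spatial position of map i is gw_i / N
  r <- rep(gw / N, each = N)
  a1 <- D1 * as.vector(p$dW1 %*% r)
  a2 <- D2 * as.vector(p$dW2 %*% a1)
  w3 <- p$dW3[classIdx, ]
  b2 <- D1 * as.vector(crossprod(p$dW2, D2 * w3))
  # dW1's rank-1 gradient b2 %o% r is assembled batched by the caller
  list(a2 = a2, dW2 = (D2 * w3) %o% a1, b2 = b2, r = r)
}

#' Prepare per-patient training samples for the MIP classifier
#'
#' Normalizes each volume, computes the coronal and sagittal MIPs and the
#' projected prior points, and checks sizes against the network
#' configuration.
#'
#' @param cohort list of [PhantomPatient-class] (or any objects with the
#'   same accessors).
#' @param config a [classifierConfig()] list.
#' @return list of samples: `mips` (named list of matrices), `p2d` (named
#'   list of `(row, col)` points), `label` (0/1), `id`.
#' @export
prepareMipSamples <- function(cohort, config) {
  lapply(cohort, function(p) {
    nv <- normalizeSuv(patientVolume(p))
    mips <- lapply(c(coronal = "coronal", sagittal = "sagittal"),
                   function(v) mipData(computeMip(nv, v)))
    for (m in mips)
      if (!all(dim(m) == config$inputShape))
        stop(sprintf("MIP is %dx%d but the network expects %dx%d",
                     nrow(m), ncol(m), config$inputShape[1], config$inputShape[2]))
    p2d <- lapply(c(coronal = "coronal", sagittal = "sagittal"), function(v)
      projectPrior(patientPrior(p), v, dim(volumeData(patientVolume(p)))))
    list(mips = mips, p2d = p2d, label = patientClass(p), id = p@id)
  })
}

#' One optimizer step on a mini-batch
#'
#' Runs the forward pass for both views of every image in the batch,
#' generates the class activation map in-graph for the true class,
#' accumulates the gradients of
#' `loss_glob = L_class + alpha * L_distance` (classification loss averaged
#' over all views; distance loss averaged over images and views), and
#' applies one Adam update. The distance term's gradient takes two
#' first-order paths: through the feature maps with the CAM weights `w_i`
#' held constant, and through the head weights defining `w_i` with the
#' activation derivatives held constant; exact backpropagation through
#' `w_i` would require second derivatives. Inside training, distances are
#' measured in units of the MIP diagonal and the heat-map mass is floored
#' (see the package vignette) so the constraint neither overwhelms the
#' classification gradient nor rewards an all-zero map.
#'
#' @param model a [MipClassifier-class].
#' @param optState Adam state from a previous step, or `NULL` to start.
#' @param batch list of samples from [prepareMipSamples()] (default size 8).
#' @param alpha distance-constraint weight; 0 gives the no-prior ablation.
#' @param lr learning rate.
#' @param lossMode `"global"` (classification + distance) or `"class"`
#'   (classification only; the CAM machinery is skipped entirely).
#' @return list: updated `model`, `optState`, and `report` with fields
#'   `lClass`, `lDistance`, `alpha`, `lossGlob`.
#' @export
trainStep <- function(model, optState, batch, alpha = 1, lr = 1e-4,
                      lossMode = c("global", "class")) {
  lossMode <- match.arg(lossMode)
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be a nonnegative number")
  cfg <- model@config
  nViews <- 2L * length(batch)
  grads <- lapply(model@params, function(p) p * 0)
  sumClass <- 0; sumDist <- 0
  # rank-1 contributions to the large first-dense-layer gradient are
  # collected and assembled in one matrix product at the end
  gzCols <- list(); vCols <- list()
  for (s in batch) {
    for (v in c("coronal", "sagittal")) {
      pred <- classifierForward(model, s$mips[[v]], train = TRUE)
      sumClass <- sumClass + classificationLoss(s$label, pred$yhat)
      dlogits <- (pred$yhat - s$label) / nViews * c(-1, 1)
      hg <- .headBackward(model, pred$headCache, dlogits, paramGrads = FALSE)
      grads$dW3 <- grads$dW3 + dlogits %o% pred$headCache$h2
      grads$db3 <- grads$db3 + hg$db3
      grads$dW2 <- grads$dW2 + hg$gz2 %o% pred$headCache$h1
      grads$db2 <- grads$db2 + hg$db2
      grads$db1 <- grads$db1 + hg$db1
      gzCols[[length(gzCols) + 1L]] <- hg$gz1
      vCols[[length(vCols) + 1L]] <- pred$headCache$V
      gFeat <- array(hg$V, dim = dim(pred$features))
      if (lossMode == "global") {
        classIdx <- s$label + 1L   # 1 = esophagus logit, 2 = lung logit
        he <- headForward(model, pred$features, train = FALSE)
        eC <- c(0, 0); eC[classIdx] <- 1
        gi <- .headBackward(model, he$cache, eC, paramGrads = FALSE)
        infl <- array(gi$V, dim = dim(pred$features))
        w <- camWeights(infl)
        dm <- .cellDistMatrix(cfg$featureShape, cfg$inputShape, s$p2d[[v]])
        dv <- .distanceGradView(pred$features, w, s$p2d[[v]], dm)
        sumDist <- sumDist + dv$loss
        if (alpha > 0) {
          gFeat <- gFeat + (alpha / nViews) * dv$gF
          hd <- .distanceHeadGrads(model, he$cache, dv$gw,
                                   dim(pred$features), classIdx)
          grads$dW3[classIdx, ] <- grads$dW3[classIdx, ] +
            (alpha / nViews) * hd$a2
          grads$dW2 <- grads$dW2 + (alpha / nViews) * hd$dW2
          gzCols[[length(gzCols) + 1L]] <- (alpha / nViews) * hd$b2
          vCols[[length(vCols) + 1L]] <- hd$r
        }
      }
      cg <- .convBackward(model, pred$convCache, gFeat)
      for (nm in names(cg)) grads[[nm]] <- grads[[nm]] + cg[[nm]]
    }
  }
  grads$dW1 <- grads$dW1 +
    tcrossprod(do.call(cbind, gzCols), do.call(cbind, vCols))
  if (any(!vapply(grads, function(g) all(is.finite(g)), TRUE)))
    stop("non-finite gradient encountered; lower the learning rate")
  if (is.null(optState)) optState <- .adamInit(model@params)
  upd <- .adamUpdate(model@params, grads, optState, lr)
  model@params <- upd$params
  lClass <- sumClass / nViews
  lDistance <- sumDist / nViews
  list(model = model, optState = upd$state,
       report = list(lClass = lClass, lDistance = lDistance, alpha = alpha,
                     lossGlob = globalLoss(lClass, lDistance, alpha)))
}

# Prior-anchored validation score: mean 3D distance (voxels) between the
# centroid of each reconstructed mask and the patient's prior point. Uses
# only the weak annotations (no ground-truth masks), and tracks
# segmentation quality far better than the training losses do, so it is
# the default model-selection criterion of the fitting routine. Empty
# masks are scored with a large constant.
.valMaskPriorScore <- function(model, valCohort, relThreshold = 0.4,
                               refine = TRUE) {
  scores <- vapply(valCohort, function(p) {
    seg <- suppressWarnings(segmentVolume(model, patientVolume(p),
                                          relThreshold = relThreshold,
                                          refine = refine))
    md <- maskData(seg$mask)
    if (sum(md) == 0L) return(100)
    cen <- colMeans(which(md == 1L, arr.ind = TRUE))
    sqrt(sum((cen - priorVoxel(patientPrior(p)))^2))
  }, 0)
  mean(scores)
}

# Evaluation-mode losses over a sample set (used for early stopping).
# Uses the same floored, diagonal-normalized distance objective as
# training, so that a collapsed heat map scores near the mean distance
# rather than zero -- otherwise model selection would favour degenerate
# maps.
.evalLosses <- function(model, samples, alpha) {
  cfg <- model@config
  sumClass <- 0; sumDist <- 0; n <- 0L
  for (s in samples) {
    for (v in c("coronal", "sagittal")) {
      pred <- classifierForward(model, s$mips[[v]])
      sumClass <- sumClass + classificationLoss(s$label, pred$yhat)
      classIdx <- s$label + 1L
      eC <- c(0, 0); eC[classIdx] <- 1
      gi <- .headBackward(model, pred$headCache, eC, paramGrads = FALSE)
      w <- camWeights(array(gi$V, dim = dim(pred$features)))
      dm <- .cellDistMatrix(cfg$featureShape, cfg$inputShape, s$p2d[[v]])
      dv <- .distanceGradView(pred$features, w, s$p2d[[v]], dm)
      sumDist <- sumDist + dv$loss
      n <- n + 1L
    }
  }
  list(lClass = sumClass / n, lDistance = sumDist / n,
       lossGlob = sumClass / n + alpha * sumDist / n)
}

#' Train the MIP classifier under the multitask objective
#'
#' Mini-batch Adam training of the shared-weight MIP classifier on a
#' cohort, with the distance constraint weighted by `alpha`
#' (`loss_glob = L_class + alpha * L_distance`). With `alpha = 0` the run
#' is exactly the classification-only ablation. Optionally early-stops on
#' the global loss of a validation cohort.
#'
#' @param cohort list of [PhantomPatient-class] for training.
#' @param config a [classifierConfig()] list.
#' @param alpha distance-constraint weight (default 1).
#' @param epochs maximum training epochs (default 100).
#' @param lr Adam learning rate (default 1e-4).
#' @param batchSize mini-batch size in images (default 8).
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @param valCohort optional validation cohort for model selection / early
#'   stopping.
#' @param valMetric model-selection criterion on the validation cohort:
#'   `"maskPrior"` (default) selects the checkpoint whose reconstructed
#'   validation masks have centroids closest to the prior points -- the
#'   only localization signal available without ground truth, and the one
#'   that tracks segmentation quality; `"loss"` selects on the validation
#'   global loss.
#' @param valEvery evaluate the selection criterion every this many epochs
#'   (after warmup plus one epoch).
#' @param patience validation evaluations without improvement before
#'   stopping.
#' @param warmupEpochs initial epochs trained with the classification loss
#'   only before the distance constraint is switched on (default 0). Until
#'   the classifier has formed, the activation maps are near-zero noise and
#'   the distance term's gradients are uninformative; a short warmup lets
#'   the constraint act on meaningful class evidence.
#' @param lossMode `"global"` or `"class"` (see [trainStep()]).
#' @param verbose print per-epoch losses.
#' @return list: `model` (the selected [MipClassifier-class]), `history`
#'   (data.frame of per-epoch `lClass`, `lDistance`, `lossGlob`,
#'   `valScore`), and `selectedEpoch`.
#' @export
fitMipClassifier <- function(cohort, config = compactClassifierConfig(),
                             alpha = 1, epochs = 100, lr = 1e-4,
                             batchSize = 8, seed = NULL, valCohort = NULL,
                             valMetric = c("maskPrior", "loss"),
                             valEvery = 2, patience = Inf, warmupEpochs = 0,
                             lossMode = c("global", "class"),
                             verbose = FALSE) {
  lossMode <- match.arg(lossMode)
  valMetric <- match.arg(valMetric)
  samples <- prepareMipSamples(cohort, config)
  valSamples <- if (!is.null(valCohort) && valMetric == "loss")
    prepareMipSamples(valCohort, config)
  .withSeed(seed, function() {
    model <- mipClassifier(config)
    optState <- NULL
    hist <- vector("list", epochs)
    best <- list(score = Inf, params = model@params, epoch = 0L)
    bad <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(length(samples))
      reports <- list()
      epAlpha <- if (ep <= warmupEpochs) 0 else alpha
      for (b in split(ord, ceiling(seq_along(ord) / batchSize))) {
        st <- trainStep(model, optState, samples[b], alpha = epAlpha, lr = lr,
                        lossMode = lossMode)
        model <- st$model
        optState <- st$optState
        reports[[length(reports) + 1L]] <- st$report
      }
      row <- data.frame(
        epoch = ep,
        lClass = mean(vapply(reports, `[[`, 0, "lClass")),
        lDistance = mean(vapply(reports, `[[`, 0, "lDistance")),
        valScore = NA_real_)
      row$lossGlob <- row$lClass + epAlpha * row$lDistance
      evalNow <- !is.null(valCohort) && ep > warmupEpochs + 1L &&
        (ep - warmupEpochs) %% valEvery == 0L
      if (evalNow) {
        score <- if (valMetric == "maskPrior") {
          .valMaskPriorScore(model, valCohort)
        } else {
          .evalLosses(model, valSamples, alpha)$lossGlob
        }
        row$valScore <- score
        if (score < best$score - 1e-9) {
          best <- list(score = score, params = model@params, epoch = ep)
          bad <- 0L
        } else bad <- bad + 1L
      }
      hist[[ep]] <- row
      if (verbose)
        message(sprintf("epoch %3d  Lclass %.4f  Ldist %.3f  glob %.4f  val %.4f",
                        ep, row$lClass, row$lDistance, row$lossGlob, row$valScore))
      if (!is.null(valCohort) && bad >= patience) break
    }
    if (!is.null(valCohort) && is.finite(best$score)) model@params <- best$params
    list(model = model, history = do.call(rbind, hist),
         selectedEpoch = best$epoch)
  })
}
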