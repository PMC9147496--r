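.maskArray <- function(x) {
  if (is(x, "TumorMask3D")) x@data else x
}

#' Dice coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are in perfect agreement and
#' score 1; an empty mask against a nonempty one scores 0.
#'
#' @param a,b binary arrays or [TumorMask3D-class] objects of equal shape.
#' @return scalar in `[0, 1]`.
#' @examples
#' diceCoef(c(1, 1, 0), c(1, 0, 1))  # |A|=|B|=2, overlap 1 -> 0.5
#' @export
diceCoef <- function(a, b) {
  a <- .maskArray(a); b <- .maskArray(b)
  if (!all(dim(a) %||% length(a) == dim(b) %||% length(b)))
    stop("masks must have the same shape")
  sa <- sum(a > 0); sb <- sum(b > 0)
  if (sa + sb == 0) return(1)
  2 * sum(a > 0 & b > 0) / (sa + sb)
}

#' Intersection over union (Jaccard index)
#'
#' `|A n B| / |A u B|`; related to dice by `iou = dice / (2 - dice)`.
#' Two empty masks score 1.
#'
#' @inheritParams diceCoef
#' @return scalar in `[0, 1]`.
#' @export
iouScore <- function(a, b) {
  a <- .maskArray(a); b <- .maskArray(b)
  if (!all(dim(a) %||% length(a) == dim(b) %||% length(b)))
    stop("masks must have the same shape")
  un <- sum(a > 0 | b > 0)
  if (un == 0) return(1)
  sum(a > 0 & b > 0) / un
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `Sens = TP/(TP+FN)`, `Spec = TN/(TN+FP)`,
#' `Acc = (TP+TN)/(TP+FN+TN+FP)`. A zero denominator yields `NA` for that
#' metric, with a warning, rather than propagating NaN.
#'
#' @param tp,fn,tn,fp nonnegative confusion counts.
#' @return list with `sens`, `spec`, `acc`.
#' @examples
#' sensSpecAcc(8, 2, 6, 4)  # 0.8, 0.6, 0.7
#' @export
sensSpecAcc <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positives: sensitivity undefined"); NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("no negatives: specificity undefined"); NA_real_
  }
  tot <- sum(counts)
  acc <- if (tot > 0) (tp + tn) / tot else {
    warning("empty confusion table: accuracy undefined"); NA_real_
  }
  list(sens = sens, spec = spec, acc = acc)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann--Whitney) AUC: the probability that a random positive
#' scores above a random negative, with ties given half credit.
#'
#' @param labels binary labels (both classes must be present).
#' @param scores numeric scores, higher = more positive.
#' @return scalar in `[0, 1]`.
#' @export
aucScore <- function(labels, scores) {
  labels <- as.integer(labels > 0)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold splits with a nested validation set
#'
#' Splits patient ids into `k` folds stratified by class label; test sets
#' are disjoint and cover the cohort. Within each fold the non-test ids
#' are further split (stratified) into train and validation, with the
#' validation set holding `valFraction` of them -- mirroring the
#' train/validation/test structure of a 115/40/40 split at n = 195.
#'
#' @param ids patient identifiers.
#' @param labels class labels, same length.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param valFraction fraction of non-test ids used for validation.
#' @return list of `k` folds, each `list(train, validation, test)` of ids.
#' @export
makeFolds <- function(ids, labels, k = 5, seed = 1, valFraction = 40 / 155) {
  stopifnot(length(ids) == length(labels))
  if (k > length(ids)) stop("k exceeds cohort size")
  classes <- unique(labels)
  if (any(table(labels) < k))
    stop("every class needs at least k members for stratified folds")
  .withSeed(seed, function() {
    foldOf <- integer(length(ids))
    off <- 0L  # rotate the remainder start across classes so fold sizes stay even
    for (cl in classes) {
      idx <- which(labels == cl)
      idx <- idx[sample(length(idx))]
      foldOf[idx] <- ((seq_along(idx) - 1L + off) %% k) + 1L
      off <- (off + length(idx)) %% k
    }
    lapply(seq_len(k), function(f) {
      testIdx <- which(foldOf == f)
      restIdx <- which(foldOf != f)
      valIdx <- integer(0)
      for (cl in classes) {
        cand <- restIdx[labels[restIdx] == cl]
        nval <- round(valFraction * length(cand))
        if (nval > 0) valIdx <- c(valIdx, sample(cand, nval))
      }
      list(train = ids[setdiff(restIdx, valIdx)],
           validation = ids[sort(valIdx)],
           test = ids[testIdx])
    })
  })
}

#' Cross-validated end-to-end evaluation of the segmentation pipeline
#'
#' For each fold: trains the MIP classifier on the training patients under
#' the multitask objective (early-stopped on the validation patients),
#' segments every held-out test patient with [segmentVolume()] using the
#' class the network predicts, and scores the 3D masks against ground
#' truth. With `alpha = 0` the same harness runs the no-prior-knowledge
#' ablation, so the two arms are directly comparable.
#'
#' @param cohort list of [PhantomPatient-class] with ground-truth masks.
#' @param alpha distance-constraint weight (0 = ablation arm).
#' @param config a [classifierConfig()] matching the cohort's MIP size.
#' @param k number of folds.
#' @param maxFolds evaluate only the first `maxFolds` folds (the split
#'   structure is still built over all `k`).
#' @param epochs,lr,batchSize,patience,warmupEpochs,valMetric,valEvery
#'   training and model-selection hyper-parameters passed to
#'   [fitMipClassifier()].
#' @param relThreshold heat-map binarization threshold.
#' @param refine apply 40%-of-SUVmax refinement inside the reconstructed
#'   prism (default `TRUE` in this harness).
#' @param seed integer seed for splits and training.
#' @return list: `perPatient` (fold, id, class, predicted class, dice,
#'   iou), `folds` (per-fold means and classifier accuracy), `aggregate`
#'   (mean and sd across folds).
#' @export
evaluatePipeline <- function(cohort, alpha = 1,
                             config = compactClassifierConfig(),
                             k = 5, maxFolds = k, epochs = 80, lr = 1e-3,
                             batchSize = 8, patience = Inf, warmupEpochs = 8,
                             valMetric = "maskPrior", valEvery = 4,
                             relThreshold = 0.4, refine = TRUE, seed = 1) {
  ids <- vapply(cohort, function(p) p@id, "")
  labels <- vapply(cohort, patientClass, 1L)
  names(cohort) <- ids
  folds <- makeFolds(ids, labels, k = k, seed = seed)
  perPatient <- list()
  foldRows <- list()
  for (f in seq_len(min(maxFolds, k))) {
    fold <- folds[[f]]
    fit <- fitMipClassifier(cohort[fold$train], config = config, alpha = alpha,
                            epochs = epochs, lr = lr, batchSize = batchSize,
                            seed = seed + f, warmupEpochs = warmupEpochs,
                            valCohort = if (length(fold$validation))
                              cohort[fold$validation],
                            valMetric = valMetric, valEvery = valEvery,
                            patience = patience)
    rows <- lapply(fold$test, function(id) {
      p <- cohort[[id]]
      seg <- segmentVolume(fit$model, patientVolume(p),
                           relThreshold = relThreshold, refine = refine)
      data.frame(fold = f, id = id,
                 class = patientClass(p),
                 predClass = as.integer(seg$class == "lung"),
                 prob = seg$prob,
                 dice = diceCoef(seg$mask, patientMask(p)),
                 iou = iouScore(seg$mask, patientMask(p)))
    })
    rows <- do.call(rbind, rows)
    perPatient[[f]] <- rows
    foldRows[[f]] <- data.frame(fold = f,
                                dice = mean(rows$dice),
                                iou = mean(rows$iou),
                                classAcc = mean(rows$class == rows$predClass))
  }
  perPatient <- do.call(rbind, perPatient)
  foldsDf <- do.call(rbind, foldRows)
  aggregate <- data.frame(
    metric = c("dice", "iou", "classAcc"),
    mean = c(mean(foldsDf$dice), mean(foldsDf$iou), mean(foldsDf$classAcc)),
    sd = c(stats::sd(foldsDf$dice), stats::sd(foldsDf$iou),
           stats::sd(foldsDf$classAcc)))
  list(perPatient = perPatient, folds = foldsDf, aggregate = aggregate,
       alpha = alpha)
}
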