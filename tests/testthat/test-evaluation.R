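test_that("dice and IoU closed forms and conventions", {
  m1 <- array(0L, c(4, 4, 4)); m1[1:2, 1, 1] <- 1L
  m2 <- array(0L, c(4, 4, 4)); m2[2:3, 1, 1] <- 1L
  expect_equal(diceCoef(m1, m1), 1)
  expect_equal(diceCoef(m1, 1L - m1), 0)
  expect_equal(diceCoef(m1, m2), 0.5)     # |A|=|B|=2, overlap 1
  expect_equal(iouScore(m1, m2), 1 / 3)
  empty <- array(0L, c(4, 4, 4))
  expect_equal(diceCoef(empty, empty), 1)
  expect_equal(diceCoef(empty, m1), 0)
  expect_equal(iouScore(empty, empty), 1)
  expect_error(diceCoef(m1, array(0L, c(3, 3, 3))), "shape")
})

test_that("iou = dice / (2 - dice) for random mask pairs", {
  set.seed(23)
  for (rep in 1:20) {
    a <- array(rbinom(216, 1, 0.3), c(6, 6, 6))
    b <- array(rbinom(216, 1, 0.3), c(6, 6, 6))
    d <- diceCoef(a, b)
    expect_equal(iouScore(a, b), d / (2 - d), tolerance = 1e-12)
  }
})

test_that("sensitivity, specificity and accuracy from confusion counts", {
  r <- sensSpecAcc(8, 2, 6, 4)
  expect_equal(r$sens, 0.8)
  expect_equal(r$spec, 0.6)
  expect_equal(r$acc, 0.7)
  perfect <- sensSpecAcc(10, 0, 10, 0)
  expect_equal(unlist(perfect), c(sens = 1, spec = 1, acc = 1))
  allPos <- sensSpecAcc(10, 0, 0, 10)
  expect_equal(unlist(allPos), c(sens = 1, spec = 0, acc = 0.5))
  expect_warning(r0 <- sensSpecAcc(0, 0, 5, 5), "sensitivity")
  expect_true(is.na(r0$sens))
  expect_error(sensSpecAcc(-1, 0, 0, 0), "nonnegative")
})

test_that("rank-based AUC matches the exhaustive pair-counting oracle and pROC", {
  expect_equal(aucScore(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(aucScore(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  set.seed(24)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 1)  # ties likely
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    wins <- 0
    for (p in pos) for (q in neg)
      wins <- wins + (p > q) + 0.5 * (p == q)
    expect_equal(aucScore(labels, scores), wins / (length(pos) * length(neg)))
    if (requireNamespace("pROC", quietly = TRUE))
      expect_equal(aucScore(labels, scores),
                   as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                  direction = "<",
                                                  levels = c(0, 1)))))
  }
  expect_error(aucScore(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("stratified folds are disjoint, covering, balanced and reproducible", {
  set.seed(25)
  n <- 195
  labels <- c(rep(1L, 98), rep(0L, 97))  # lung / esophageal
  ids <- sprintf("P%03d", seq_len(n))
  folds <- makeFolds(ids, labels, k = 5, seed = 31)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), sort(ids))          # coverage
  expect_equal(length(unique(unlist(tests))), n)        # disjoint
  sizes <- lengths(tests)
  expect_true(all(sizes %in% c(39L, 40L)))
  globalRatio <- mean(labels == 1L)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$validation, f$test), 0)
    expect_length(intersect(f$train, f$validation), 0)
    testLab <- labels[match(f$test, ids)]
    expect_lte(abs(sum(testLab) - globalRatio * length(testLab)), 1)
    # nested validation split mimics the 115/40/40 structure
    expect_gt(length(f$validation), 0.15 * (n - length(f$test)))
    expect_lt(length(f$validation), 0.35 * (n - length(f$test)))
  }
  expect_identical(makeFolds(ids, labels, k = 5, seed = 31), folds)
  expect_false(identical(makeFolds(ids, labels, k = 5, seed = 32), folds))
  expect_error(makeFolds(ids[1:6], c(1, 1, 1, 0, 0, 1), k = 5), "at least k")
})

test_that("the evaluation harness aggregates per-fold metrics and is reproducible", {
  co <- cachedSmallCohort(10, seed = 12)
  rep1 <- evaluatePipeline(co, alpha = 1, config = smallNetConfig(), k = 2,
                           epochs = 2, lr = 1e-3, seed = 3)
  expect_equal(nrow(rep1$folds), 2)
  expect_equal(nrow(rep1$perPatient), 10)
  expect_equal(rep1$aggregate$mean[rep1$aggregate$metric == "dice"],
               mean(rep1$folds$dice))
  expect_equal(rep1$aggregate$mean[rep1$aggregate$metric == "classAcc"],
               mean(rep1$folds$classAcc))
  expect_true(all(rep1$perPatient$dice >= 0 & rep1$perPatient$dice <= 1))
  rep2 <- evaluatePipeline(co, alpha = 1, config = smallNetConfig(), k = 2,
                           epochs = 2, lr = 1e-3, seed = 3)
  expect_identical(rep1$perPatient$dice, rep2$perPatient$dice)
})
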