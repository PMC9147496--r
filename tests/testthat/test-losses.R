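test_that("binary cross-entropy closed forms and batch averaging", {
  expect_lt(classificationLoss(1, 1 - 1e-7), 1e-6)
  expect_equal(classificationLoss(1, 0.5), log(2))
  expect_equal(classificationLoss(0, 0.5), log(2))
  # boundary predictions are clamped, not infinite
  expect_true(is.finite(classificationLoss(c(1, 0), c(0, 1))))
  set.seed(14)
  y <- rbinom(4, 1, 0.5); p <- runif(4, 0.05, 0.95)
  oracle <- 0
  for (i in 1:4) oracle <- oracle - (y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
  expect_equal(classificationLoss(y, p), oracle / 4)
  expect_error(classificationLoss(c(1, 0), 0.5), "length")
})

test_that("distance loss: point masses, uniform maps, and the zero convention", {
  h <- matrix(0, 9, 9); h[5, 5] <- 1
  expect_equal(distanceLoss(h, c(5, 5)), 0)
  h2 <- matrix(0, 9, 9); h2[5, 9] <- 0.37   # scale must not matter
  expect_equal(distanceLoss(h2, c(5, 4)), 5)
  u <- matrix(1, 3, 3)
  expect_equal(distanceLoss(u, c(2, 2)), (0 + 4 * 1 + 4 * sqrt(2)) / 9)
  expect_equal(distanceLoss(matrix(0, 4, 4), c(2, 2)), 0)
  expect_error(distanceLoss(u, c(9, 2)), "outside")
})

test_that("distance loss is translation-consistent and increases as mass moves away", {
  h <- matrix(0, 12, 12); h[3, 4] <- 1; h[4, 5] <- 0.5
  shifted <- matrix(0, 12, 12); shifted[3 + 5, 4 + 2] <- 1; shifted[4 + 5, 5 + 2] <- 0.5
  expect_equal(distanceLoss(h, c(3, 5)), distanceLoss(shifted, c(8, 7)))
  # moving a fixed point mass strictly farther increases the loss
  prev <- -1
  for (col in 3:10) {
    m <- matrix(0, 12, 12); m[6, col] <- 1
    cur <- distanceLoss(m, c(6, 2))
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("the global loss is the exact weighted sum with alpha defaulting to 1", {
  expect_equal(globalLoss(0.5, 2, alpha = 1), 2.5)
  expect_equal(globalLoss(0.7, 123, alpha = 0), 0.7)
  expect_equal(formals(globalLoss)$alpha, 1)
  expect_error(globalLoss(1, 1, alpha = -0.1), "alpha")
})

test_that("distance-objective feature gradients match finite differences (weights and scale frozen)", {
  set.seed(15)
  cfg <- tinyNetConfig()
  J <- cfg$featureShape[1]; Zc <- cfg$featureShape[2]; D <- cfg$featureShape[3]
  f <- array(rnorm(J * Zc * D, 0.3, 0.5), c(J, Zc, D))
  w <- c(0.8, -0.3)
  p2d <- c(9, 4); Temp <- 0.15  # explicit, not the default
  dm <- petcam:::.cellDistMatrix(cfg$featureShape, cfg$inputShape, p2d)
  dv <- petcam:::.distanceGradView(f, w, p2d, dm, Temp = Temp)
  # the objective is the softmax-attention-weighted mean cell distance;
  # the scale normalization is held constant in the backward pass
  sc <- 1 / (max(abs(preHeatmap(f, w))) + 1e-8)
  lossOf <- function(g) {
    z <- preHeatmap(g, w) * (sc / Temp)
    a <- exp(z - max(z)); a <- a / sum(a)
    sum(a * dm)
  }
  expect_equal(dv$loss, lossOf(f))
  h <- 1e-6
  fd <- array(0, dim(f))
  for (i in seq_along(fd)) {
    fp <- f; fp[i] <- fp[i] + h
    fm <- f; fm[i] <- fm[i] - h
    fd[i] <- (lossOf(fp) - lossOf(fm)) / (2 * h)
  }
  expect_lt(max(abs(dv$gF - fd)), 1e-5 * max(1, max(abs(fd))))
  # attention all at the prior cell -> loss 0; far point mass -> larger
  expect_gte(min(dm), 0)
  expect_lt(dv$loss, max(dm))
})

test_that("every training step reports loss_glob = L_class + alpha * L_distance", {
  co <- cachedSmallCohort(6, seed = 1)
  cfg <- smallNetConfig()
  samples <- prepareMipSamples(co, cfg)
  model <- mipClassifier(cfg, seed = 1)
  st <- NULL
  for (alpha in c(1, 0.5)) {
    opt <- NULL; m <- model
    for (k in 1:3) {
      st <- trainStep(m, opt, samples, alpha = alpha, lr = 1e-3)
      m <- st$model; opt <- st$optState
      r <- st$report
      expect_equal(r$lossGlob, r$lClass + alpha * r$lDistance)
      expect_gte(r$lClass, 0)
      expect_gte(r$lDistance, 0)
    }
  }
})

test_that("alpha = 0 training is bit-identical to the classification-only run", {
  co <- cachedSmallCohort(6, seed = 1)
  cfg <- smallNetConfig()
  a <- fitMipClassifier(co, cfg, alpha = 0, epochs = 2, lr = 1e-3, seed = 77)
  b <- fitMipClassifier(co, cfg, alpha = 0, epochs = 2, lr = 1e-3, seed = 77,
                        lossMode = "class")
  expect_identical(a$model@params, b$model@params)
  expect_identical(a$history$lClass, b$history$lClass)
})

test_that("the global loss decreases over a short training run on a toy cohort", {
  co <- cachedSmallCohort(16, seed = 6)
  fit <- fitMipClassifier(co, smallNetConfig(), alpha = 1, epochs = 25,
                          lr = 1e-3, seed = 5)
  h <- fit$history
  expect_lt(mean(tail(h$lossGlob, 3)), mean(head(h$lossGlob, 3)))
  expect_lt(mean(tail(h$lClass, 3)), mean(head(h$lClass, 3)))
})
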