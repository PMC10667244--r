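# brute-force double-sum oracle for the mini-batch averaged MSE
bruteMse <- function(X, Xh) {
  N <- ncol(X); M <- nrow(X)
  tot <- 0
  for (j in seq_len(N)) {
    s <- 0
    for (i in seq_len(M)) s <- s + (X[i, j] - Xh[i, j])^2
    tot <- tot + s / M
  }
  tot / N
}

test_that("mseLoss equals the brute-force double summation", {
  x <- matrix(c(0, 0, 1, 1), ncol = 1)
  xh <- matrix(c(0, 1, 1, 0), ncol = 1)
  expect_equal(mseLoss(x, xh), 0.5)
  expect_equal(mseLoss(x, x), 0)
  set.seed(10)
  for (rep in 1:20) {
    X <- matrix(runif(64 * 3), 64, 3)
    Xh <- matrix(runif(64 * 3), 64, 3)
    expect_rel_equal(mseLoss(X, Xh), bruteMse(X, Xh), tol = 1e-12)
  }
  expect_error(mseLoss(matrix(0, 2, 2), matrix(0, 2, 3)),
               "shape mismatch")
})

test_that("fusedLoss is the affine combination with exact boundaries", {
  set.seed(11)
  b2 <- matrix(runif(32 * 4), 32); b2h <- matrix(runif(32 * 4), 32)
  b3 <- matrix(runif(64 * 4), 64); b3h <- matrix(runif(64 * 4), 64)
  expect_identical(fusedLoss(b2, b2h, b3, b3h, w1 = 1), mseLoss(b2, b2h))
  expect_identical(fusedLoss(b2, b2h, b3, b3h, w1 = 0), mseLoss(b3, b3h))
  expect_equal(fusedLoss(b2, b2h, b3, b3h, 0.5),
               0.5 * mseLoss(b2, b2h) + 0.5 * mseLoss(b3, b3h))
  # affine in w1
  w <- runif(5)
  l <- vapply(w, function(wi) fusedLoss(b2, b2h, b3, b3h, wi), 0)
  expect_rel_equal(l, w * mseLoss(b2, b2h) + (1 - w) * mseLoss(b3, b3h),
                   tol = 1e-12)
  expect_error(fusedLoss(b2, b2h, b3, b3h, 1.2), "w1")
})

test_that("analytic MSE gradient matches central finite differences", {
  set.seed(12)
  X <- matrix(runif(24), 24, 1)
  Xh <- matrix(runif(24), 24, 1)
  g <- 2 * (Xh - X) / length(X)    # d mseLoss / d xhat
  eps <- 1e-6
  for (i in c(1L, 7L, 24L)) {
    xp <- Xh; xp[i] <- xp[i] + eps
    xm <- Xh; xm[i] <- xm[i] - eps
    num <- (mseLoss(X, xp) - mseLoss(X, xm)) / (2 * eps)
    expect_lt(abs(num - g[i]) / max(abs(num), 1e-12), 1e-4)
  }
})

test_that("buildDCAE honors the encode/decode shape contract", {
  cfg <- dcaeConfig("3d", convChannels = c(8L, 16L), latentDim = 16L,
                    inputShape3d = c(32L, 32L, 32L), seed = 1L)
  m <- buildDCAE(cfg)
  x <- matrix(runif(32^3), ncol = 1)
  z <- DCAEC:::nnForward(m@net$enc, x)$out
  expect_equal(dim(z), c(16L, 1L))
  xhat <- DCAEC:::nnForward(m@net$dec, z)$out
  expect_equal(nrow(xhat), 32L^3)
  expect_true(all(xhat >= 0 & xhat <= 1))  # sigmoid output range
})

test_that("parameter initialization is seed-reproducible", {
  cfg <- tinyConfig3d(seed = 21L)
  expect_identical(modelParameters(buildDCAE(cfg)),
                   modelParameters(buildDCAE(cfg)))
  cfg2 <- tinyConfig3d(seed = 22L)
  expect_false(identical(modelParameters(buildDCAE(cfg)),
                         modelParameters(buildDCAE(cfg2))))
})

test_that("incompatible shape/stride combinations name the offending layer", {
  cfg <- dcaeConfig("3d", convChannels = c(8L, 16L), latentDim = 8L,
                    inputShape3d = c(30L, 30L, 30L), seed = 1L)
  expect_error(buildDCAE(cfg), "conv layer 2")
  cfg1 <- dcaeConfig("3d", convChannels = 8L, latentDim = 8L,
                     inputShape3d = c(15L, 15L, 15L), seed = 1L)
  expect_error(buildDCAE(cfg1), "conv layer 1")
})

test_that("training reduces reconstruction loss on synthetic volumes", {
  m <- tinyTrained3d()
  h <- lossHistory(m)
  expect_lt(h[length(h)], h[1])
  expect_true(all(is.finite(h)))
})

test_that("all-zero images are a reachable fixed point of training", {
  zeros <- cellDataset(volumes = array(0, c(16L, 8L, 8L, 8L)),
                       preprocessed = TRUE)
  cfg <- dcaeConfig("3d", convChannels = 4L, latentDim = 4L,
                    epochs = 150L, batchSize = 4L, learningRate = 5e-2,
                    inputShape3d = c(8L, 8L, 8L), seed = 2L)
  m <- trainDCAE(buildDCAE(cfg), zeros)
  expect_lt(min(lossHistory(m)), 1e-3)
})

test_that("fused training with w1 = 1 reproduces 2D-only training", {
  tf <- tinyTrainedFused()
  ds <- tf$ds
  cfgF <- dcaeConfig("fused", convChannels = c(4L, 8L), latentDim = 8L,
                     epochs = 3L, batchSize = 16L, w1 = 1,
                     inputShape2d = c(16L, 16L),
                     inputShape3d = c(16L, 16L, 16L), seed = 31L)
  mF <- trainDCAE(buildDCAE(cfgF), ds)
  cfg2 <- dcaeConfig("2d", convChannels = c(4L, 8L), latentDim = 8L,
                     epochs = 3L, batchSize = 16L,
                     inputShape2d = c(16L, 16L), seed = 31L)
  m2 <- trainDCAE(buildDCAE(cfg2), ds)
  expect_identical(lossHistory(mF), lossHistory(m2))
  # with w1 = 1 the 3D branch receives zero gradient and never moves
  fresh <- buildDCAE(cfgF)
  expect_identical(c(DCAEC:::paramVector(mF@net$m3d$enc),
                     DCAEC:::paramVector(mF@net$m3d$dec)),
                   c(DCAEC:::paramVector(fresh@net$m3d$enc),
                     DCAEC:::paramVector(fresh@net$m3d$dec)))
})

test_that("encoding returns one deterministic code per cell", {
  m <- tinyTrained3d()
  ds <- tinyDataset3d()
  Z <- encodeCells(m, ds)
  expect_equal(dim(Z), c(24L, 8L))
  expect_identical(Z, encodeCells(m, ds))
  tf <- tinyTrainedFused()
  Zf <- encodeCells(tf$model, tf$ds)
  expect_equal(ncol(Zf), 16L)  # n2d + n3d concatenated
  # concatenation order is (2d, 3d)
  z2 <- t(DCAEC:::encodeBatched(tf$model@net$m2d$enc,
                                DCAEC:::datasetTensor(tf$ds, "2d")))
  expect_identical(Zf[, 1:8], z2)
  expect_no_error(encodeCells(m, tf$ds[1:4]))  # 3d data present, works
  ds2only <- cellDataset(images = images2d(tf$ds), preprocessed = TRUE)
  expect_error(encodeCells(m, ds2only), "modality mismatch")
})

test_that("autoencoder identifies a rank-limited image family", {
  # discs varying along one latent factor (radius); a constant-image
  # predictor cannot track the moving boundary, an autoencoder can
  set.seed(6)
  n <- 40L; H <- 16L
  radii <- runif(n, 3, 6.5)
  dist <- DCAEC:::radialDistance(c(H, H), c(8.5, 8.5))
  imgs <- array(0, c(n, H, H))
  for (i in seq_len(n))
    imgs[i, , ] <- 1 / (1 + exp((dist - radii[i]) / 0.7))
  ds <- cellDataset(images = imgs, preprocessed = TRUE)
  cfg <- dcaeConfig("2d", convChannels = c(4L, 8L), latentDim = 4L,
                    epochs = 60L, batchSize = 16L, learningRate = 3e-3,
                    inputShape2d = c(H, H), seed = 6L)
  m <- trainDCAE(buildDCAE(cfg), ds)
  X <- DCAEC:::datasetTensor(ds, "2d")
  rec <- DCAEC:::nnForward(c(m@net$enc, m@net$dec), X)$out
  constLoss <- mean((X - rowMeans(X))^2)
  expect_lt(mseLoss(X, rec), constLoss)
})
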