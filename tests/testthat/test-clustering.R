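# Mclust resolves helper functions in its calling environment, so the
# namespace must be attached
suppressPackageStartupMessages(library(mclust))

twoBlobs <- function(n = 200L, sep = 20, seed = 1L, dim = 2L) {
  set.seed(seed)
  half <- n %/% 2L
  Z <- rbind(matrix(rnorm(half * dim), ncol = dim),
             matrix(rnorm((n - half) * dim), ncol = dim))
  Z[seq_len(half), 1L] <- Z[seq_len(half), 1L] - sep / 2
  Z[(half + 1L):n, 1L] <- Z[(half + 1L):n, 1L] + sep / 2
  list(Z = Z, y = rep(0:1, c(half, n - half)))
}

test_that("transferred encoders are bit-identical and decoder-free", {
  m <- tinyTrained3d()
  enc <- transferEncoder(m)
  expect_identical(modelParameters(enc),
                   DCAEC:::paramVector(m@net$enc))
  expect_lt(length(modelParameters(enc)), length(modelParameters(m)))
  ds <- tinyDataset3d()
  expect_identical(encodeWithEncoder(enc, ds), encodeCells(m, ds))
  un <- buildDCAE(tinyConfig3d())
  expect_error(transferEncoder(un), "untrained")
})

test_that("fused transfer concatenates codes in fixed (2d, 3d) order", {
  tf <- tinyTrainedFused()
  enc <- transferEncoder(tf$model)
  Z <- encodeWithEncoder(enc, tf$ds)
  z2 <- t(DCAEC:::encodeBatched(tf$model@net$m2d$enc,
                                DCAEC:::datasetTensor(tf$ds, "2d")))
  z3 <- t(DCAEC:::encodeBatched(tf$model@net$m3d$enc,
                                DCAEC:::datasetTensor(tf$ds, "3d")))
  expect_identical(Z, cbind(z2, z3))
})

test_that("GMM recovers well-separated Gaussian blobs exactly", {
  b <- twoBlobs(seed = 42L)
  res <- fitGMM(b$Z, gmmConfig(K = 2L, seed = 1L))
  expect_equal(mclust::adjustedRandIndex(predictedLabels(res), b$y), 1.0)
  R <- responsibilities(res)
  expect_true(all(abs(rowSums(R) - 1) < 1e-9))
  expect_lt(abs(sum(gmmParams(res)$weights) - 1), 1e-9)
})

test_that("EM log-likelihood is non-decreasing", {
  set.seed(7)
  Z <- rbind(matrix(rnorm(120, sd = 1.4), ncol = 3),
             matrix(rnorm(90, mean = 2), ncol = 3))
  for (form in c("full", "diagonal")) {
    res <- fitGMM(Z, gmmConfig(K = 3L, covarianceForm = form, seed = 2L))
    ll <- logLikHistory(res)
    expect_true(all(diff(ll) >= -1e-8))
  }
})

test_that("single-component and undersized inputs behave as contracted", {
  set.seed(8)
  Z <- matrix(rnorm(30), ncol = 3)
  res <- fitGMM(Z, gmmConfig(K = 1L, seed = 1L))
  expect_true(all(predictedLabels(res) == 0L))
  expect_equal(gmmParams(res)$weights, 1.0)
  expect_error(fitGMM(Z[1:2, ], gmmConfig(K = 3L)), "cells < K")
})

test_that("identical latent codes are regularized with a warning", {
  Z <- matrix(1, 20, 4)
  expect_warning(res <- fitGMM(Z, gmmConfig(K = 2L, seed = 1L)),
                 "regularized")
  expect_length(predictedLabels(res), 20L)
})

test_that("EM beats every hard-assignment mixture on tiny 1D instances", {
  # brute-force oracle: enumerate all 2-part labelings of <= 8 points,
  # score the mixture likelihood under each labeling's MLE parameters
  hardBound <- function(z, reg = 1e-6) {
    n <- length(z)
    best <- -Inf
    for (code in 1:(2^n - 2)) {
      lab <- as.integer(intToBits(code))[1:n]
      if (sum(lab) == 0 || sum(lab) == n) next
      ll <- 0
      w <- c(mean(lab == 0), mean(lab == 1))
      mus <- c(mean(z[lab == 0]), mean(z[lab == 1]))
      vars <- c(mean((z[lab == 0] - mus[1])^2),
                mean((z[lab == 1] - mus[2])^2)) + reg
      dens <- sapply(1:2, function(k)
        w[k] * stats::dnorm(z, mus[k], sqrt(vars[k])))
      ll <- sum(log(rowSums(dens)))
      best <- max(best, ll)
    }
    best
  }
  for (seed in 1:3) {
    set.seed(seed)
    z <- c(rnorm(4, -2, 0.5), rnorm(3, 2, 0.5))
    res <- fitGMM(matrix(z, ncol = 1),
                  gmmConfig(K = 2L, kmeansRestarts = 10L, seed = seed))
    ll <- logLikHistory(res)
    expect_gte(ll[length(ll)] + 1e-6, hardBound(z))
  }
})

test_that("clustering is permutation-equivariant up to component relabeling", {
  b <- twoBlobs(n = 120L, seed = 9L)
  res1 <- fitGMM(b$Z, gmmConfig(K = 2L, seed = 3L))
  set.seed(99); perm <- sample.int(120L)
  res2 <- fitGMM(b$Z[perm, ], gmmConfig(K = 2L, seed = 3L))
  expect_equal(mclust::adjustedRandIndex(predictedLabels(res1)[perm],
                                         predictedLabels(res2)), 1.0)
})

test_that("fitGMM agrees with an independent GMM implementation", {
  b <- twoBlobs(n = 150L, sep = 8, seed = 5L, dim = 3L)
  res <- fitGMM(b$Z, gmmConfig(K = 2L, seed = 1L))
  mc <- mclust::Mclust(b$Z, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(mclust::adjustedRandIndex(predictedLabels(res),
                                         mc$classification), 1.0)
  expect_lt(abs(res@logLikHistory[length(res@logLikHistory)] - mc$loglik),
            0.05 * abs(mc$loglik))
})

test_that("clusterDataset composes transfer, encode and GMM deterministically", {
  m <- tinyTrained3d()
  ds <- tinyDataset3d()
  cfg <- gmmConfig(K = 2L, seed = 4L)
  res <- clusterDataset(m, ds, cfg)
  expect_setequal(unique(predictedLabels(res)), c(0L, 1L))
  manual <- fitGMM(encodeWithEncoder(transferEncoder(m), ds), cfg)
  expect_identical(predictedLabels(res), predictedLabels(manual))
  expect_identical(predictedLabels(res),
                   predictedLabels(clusterDataset(m, ds, cfg)))
})
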