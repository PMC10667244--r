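tinyClassifier <- function() memoize("classifier", function() {
  tf <- tinyTrainedFused()
  res <- clusterDataset(tf$model, tf$ds, gmmConfig(K = 2L, seed = 5L))
  cls <- trainClusterClassifier(tf$model, tf$ds, predictedLabels(res),
                                epochs = 40L, seed = 5L)
  list(cls = cls, ds = tf$ds, model = tf$model,
       clusters = predictedLabels(res))
})

# hand-built classifier: 1x1 conv passthrough + linear head directly on the
# flattened activation map, so d y^c / d A is exactly the head weight row
handClassifier <- function(headRow, H = 2L, W = 2L) {
  conv <- DCAEC:::layerConv(c(1L, 1L, H, W), 1L, c(1L, 1L, 1L),
                            c(1L, 1L, 1L))
  conv$W <- matrix(1, 1, 1); conv$b <- 0.5  # keeps activations positive
  fc <- DCAEC:::layerFC(H * W, 2L)
  fc$W <- rbind(headRow, 0)
  fc$b <- c(0, 0)
  new("ClusterClassifier", encoder = list(conv, DCAEC:::layerReLU()),
      head = list(fc), nClasses = 2L, inputShape = c(1L, H, W),
      history = numeric(0))
}

test_that("Grad-CAM weights are the global average of the score gradient", {
  # gradient map [[1,2],[3,4]] (h-fastest layout c(1,3,2,4)) -> weight 2.5
  cls <- handClassifier(c(1, 3, 2, 4))
  img <- matrix(runif(4), 2, 2)
  w <- gradcamWeights(cls, img, targetClass = 0L)
  expect_equal(as.numeric(w), 2.5)
  # constant gradient g over the map -> weight g
  clsG <- handClassifier(rep(0.7, 4))
  expect_equal(as.numeric(gradcamWeights(clsG, img, 0L)), 0.7)
  expect_error(gradcamWeights(cls, img, 5L), "out of range")
})

test_that("backprop activation gradients match finite differences", {
  fx <- tinyClassifier()
  cls <- fx$cls
  img <- images2d(fx$ds)[1, , ]
  loc <- DCAEC:::convActivationIndex(cls@encoder, NULL)
  layers <- c(cls@encoder, cls@head)
  x <- matrix(as.numeric(img), ncol = 1)
  fw <- DCAEC:::nnForwardAll(layers, x)
  dOut <- matrix(c(1, 0), 2, 1)
  bw <- DCAEC:::nnBackward(layers, fw$caches, dOut,
                           stopAfter = loc$reluIdx)
  A <- fw$outs[[loc$reluIdx]]
  sub <- layers[(loc$reluIdx + 1L):length(layers)]
  yc <- function(a) DCAEC:::nnForward(sub, a)$out[1L, 1L]
  set.seed(1)
  idx <- sample(length(A), 8L)
  eps <- 1e-5
  for (i in idx) {
    ap <- A; ap[i] <- ap[i] + eps
    am <- A; am[i] <- am[i] - eps
    num <- (yc(ap) - yc(am)) / (2 * eps)
    expect_lt(abs(num - bw$dX[i]), 1e-3 * max(1, abs(num)))
  }
  # and the exported weights are exactly the per-map average
  w <- gradcamWeights(cls, img, 0L)
  od <- loc$outDim
  expect_equal(as.numeric(w),
               colMeans(matrix(bw$dX, prod(od[2:4]), od[1L])))
})

test_that("gradcamMap is the ReLU of the weighted activation combination", {
  A1 <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  A2 <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  hm <- gradcamMap(list(A1, A2), c(1, -2))
  expect_equal(hm@values, matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  # all-negative weights on positive activations annihilate
  hm0 <- gradcamMap(list(A1 + 1, A2 + 1), c(-1, -2))
  expect_true(all(hm0@values == 0))
  # single map, weight 1 -> ReLU(A)
  A3 <- matrix(c(-1, 2, -3, 4), 2)
  expect_equal(gradcamMap(list(A3), 1)@values, pmax(A3, 0))
  expect_error(gradcamMap(list(A1, A2), c(1, 2, 3)), "shape mismatch")
})

test_that("brute-force Eq-style loops agree with gradcamMap on random stacks", {
  set.seed(2)
  for (rep in 1:20) {
    K <- sample(2:5, 1)
    A <- array(rnorm(6 * 7 * K), c(6, 7, K))
    w <- rnorm(K)
    hm <- gradcamMap(A, w)
    brute <- matrix(0, 6, 7)
    for (i in 1:6) for (j in 1:7) {
      s <- 0
      for (k in 1:K) s <- s + w[k] * A[i, j, k]
      brute[i, j] <- max(0, s)
    }
    expect_rel_equal(hm@values, brute, tol = 1e-12)
  }
})

test_that("heatmapToMask thresholds as specified", {
  cb <- matrix(rep(c(0, 1), 8), 4, 4)
  hm <- new("Heatmap", values = cb, targetClass = 0L)
  mask <- heatmapToMask(hm, c(4L, 4L), "fraction_of_max", fraction = 0.5)
  expect_equal(mask@pixels, cb == 1)
  z <- new("Heatmap", values = matrix(0, 3, 3), targetClass = 1L)
  mz <- heatmapToMask(z, c(6L, 6L))
  expect_false(any(mz@pixels))
  expect_equal(mz@sourceClass, 1L)
  expect_error(heatmapToMask(hm, c(4L, 4L), "fraction_of_max", 1.5),
               "fraction")
})

test_that("Otsu threshold maximizes between-class variance", {
  set.seed(3)
  v <- c(rnorm(300, 0.15, 0.04), rnorm(200, 0.8, 0.05))
  v <- pmin(pmax(v, 0), 1)
  thr <- otsuThreshold(v)
  # exhaustive oracle over candidate thresholds
  cands <- seq(0.01, 0.99, by = 0.002)
  bcv <- vapply(cands, function(t) {
    w0 <- mean(v < t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    w0 * w1 * (mean(v[v < t]) - mean(v[v >= t]))^2
  }, 0)
  bestT <- cands[which.max(bcv)]
  expect_identical(v >= thr, v >= bestT)
})

test_that("classifier fine-tuning never touches the frozen encoder", {
  fx <- tinyClassifier()
  expect_identical(DCAEC:::paramVector(fx$cls@encoder),
                   DCAEC:::paramVector(fx$model@net$m2d$enc))
  expect_error(trainClusterClassifier(fx$model, fx$ds, rep(0L, 40)),
               "single class")
  expect_error(trainClusterClassifier(fx$model, fx$ds, c(0L, 1L)),
               "length mismatch")
})

test_that("the head learns separable cluster labels", {
  fx <- tinyClassifier()
  pred <- classifierPredict(fx$cls, fx$ds)
  expect_gte(mean(pred == fx$clusters), 0.95)
})

test_that("cluster masks are more alike within than across clusters", {
  fx <- tinyClassifier()
  masks <- computeClusterMasks(fx$cls, fx$ds, fx$clusters)
  iou <- function(a, b) {
    u <- sum(a | b)
    if (u == 0) return(1)
    sum(a & b) / u
  }
  px <- lapply(masks, function(m) m@pixels)
  cl <- fx$clusters
  within <- c(); across <- c()
  set.seed(4)
  for (rep in 1:200) {
    ij <- sample(length(px), 2L)
    v <- iou(px[[ij[1]]], px[[ij[2]]])
    if (cl[ij[1]] == cl[ij[2]]) within <- c(within, v)
    else across <- c(across, v)
  }
  expect_gt(mean(within), mean(across))
})

test_that("fivefold mask CV separates constructed patterns", {
  fx <- generateMaskFixtures(20L, shape = c(16L, 16L),
                             pattern = "half_split", noiseFlipProb = 0,
                             seed = 8L)
  cv <- fiveFoldMaskCV(fx$masks, seed = 1L, epochs = 15L)
  # partition invariants
  expect_length(cv$foldAssignment, 40L)
  expect_setequal(unique(cv$foldAssignment), 1:5)
  expect_equal(as.numeric(table(cv$foldAssignment)), rep(8, 5))
  expect_equal(vapply(cv$folds, `[[`, 0, "accuracy"), rep(1, 5))
  expect_equal(cv$meanAUC, 1)
  noisy <- generateMaskFixtures(20L, shape = c(16L, 16L),
                                pattern = "half_split",
                                noiseFlipProb = 0.1, seed = 8L)
  cvN <- fiveFoldMaskCV(noisy$masks, seed = 1L, epochs = 15L)
  expect_gte(cvN$meanAccuracy, 0.9)
  expect_error(fiveFoldMaskCV(fx$masks[c(1:4, 21:24)]), "5 masks per class")
})
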