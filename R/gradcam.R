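# Grad-CAM interpretation of cluster assignments.
#
# A CNN classifier is formed from the frozen, transferred DCAE encoder plus
# two fine-tuned fully connected layers trained on *cluster* labels (not
# truth labels). Relevance maps come from the gradients of the pre-softmax
# class score with respect to the feature maps of a convolutional layer
# (default: the last encoder conv layer), global-average-pooled into
# per-map weights and combined through a ReLU. Heatmaps are normalized,
# bilinearly upsampled to input resolution and thresholded into binary
# masks whose cluster specificity is validated by stratified fivefold
# cross-validated CNN classification.

softmaxCols <- function(L) {
  m <- apply(L, 2L, max)
  E <- exp(sweep(L, 2L, m))
  sweep(E, 2L, colSums(E), "/")
}

# mini-batch cross-entropy training of a layer stack; y is 0-based
trainSoftmaxNet <- function(layers, X, y, epochs, lr, batchSize = 32L) {
  state <- adamInit(layers)
  n <- ncol(X)
  C <- max(y) + 1L
  history <- numeric(epochs)
  t <- 0L
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = batchSize)) {
      idx <- perm[start:min(start + batchSize - 1L, n)]
      xb <- X[, idx, drop = FALSE]
      yb <- y[idx]
      fw <- nnForward(layers, xb)
      P <- softmaxCols(fw$out)
      picked <- P[cbind(yb + 1L, seq_along(idx))]
      loss <- -mean(log(pmax(picked, 1e-12)))
      Y <- matrix(0, nrow(P), length(idx))
      Y[cbind(yb + 1L, seq_along(idx))] <- 1
      dL <- (P - Y) / length(idx)
      bw <- nnBackward(layers, fw$caches, dL)
      t <- t + 1L
      upd <- adamStep(layers, bw$grads, state, lr, t)
      layers <- upd$layers; state <- upd$state
      tot <- tot + loss * length(idx)
    }
    history[ep] <- tot / n
  }
  list(layers = layers, history = history)
}

#' Train the cluster-label classifier on a frozen encoder
#'
#' Builds the interpretation CNN: the encoder transferred from the trained
#' DCAE (2D sub-model for fused models, following the convention of
#' interpreting the transmission modality) stays frozen; a two-layer fully
#' connected head is trained with cross-entropy to predict the *cluster*
#' labels produced by \code{\link{clusterDataset}}. Because the encoder is
#' frozen, its latent codes are precomputed once and only the head sees
#' gradient updates — the encoder parameter vector is bit-identical before
#' and after training.
#'
#' @param trainedDcae a trained \linkS4class{DCAEModel}.
#' @param dataset the preprocessed \linkS4class{CellDataset}.
#' @param clusterLabels integer cluster label per cell (0-based).
#' @param epochs,lr,hidden head training settings.
#' @param seed RNG seed.
#' @return a \linkS4class{ClusterClassifier}.
#' @export
trainClusterClassifier <- function(trainedDcae, dataset, clusterLabels,
                                   epochs = 50L, lr = 1e-3, hidden = 64L,
                                   seed = 1L) {
  n <- nCells(dataset)
  if (length(clusterLabels) != n)
    stop("label/data length mismatch")
  clusterLabels <- as.integer(clusterLabels)
  C <- length(unique(clusterLabels))
  if (C < 2L) stop("cluster labels contain a single class")
  cfg <- trainedDcae@config
  if (trainedDcae@modality == "fused") {
    enc <- trainedDcae@net$m2d$enc
    shape <- c(1L, cfg$inputShape2d)
    mod <- "2d"
  } else {
    enc <- trainedDcae@net$enc
    shape <- if (trainedDcae@modality == "2d") c(1L, cfg$inputShape2d)
             else cfg$inputShape3d
    mod <- trainedDcae@modality
  }
  X <- datasetTensor(dataset, mod)
  Z <- encodeBatched(enc, X)           # latent x N, frozen features
  set.seed(seed)
  head <- list(layerFC(nrow(Z), hidden), layerReLU(), layerFC(hidden, C))
  res <- trainSoftmaxNet(head, Z, clusterLabels, epochs, lr)
  new("ClusterClassifier", encoder = enc, head = res$layers,
      nClasses = as.integer(C), inputShape = as.integer(shape),
      history = res$history)
}

#' Classifier logits and predictions
#'
#' @param classifier a \linkS4class{ClusterClassifier}.
#' @param dataset a \linkS4class{CellDataset} (modality matching the
#'   classifier's encoder).
#' @return \code{classifierLogits}: classes-by-cells matrix of pre-softmax
#'   scores; \code{classifierPredict}: 0-based predicted labels.
#' @export
classifierLogits <- function(classifier, dataset) {
  mod <- if (classifier@inputShape[1L] == 1L) "2d" else "3d"
  X <- datasetTensor(dataset, mod)
  Z <- encodeBatched(classifier@encoder, X)
  nnForward(classifier@head, Z)$out
}

#' @rdname classifierLogits
#' @export
classifierPredict <- function(classifier, dataset) {
  max.col(t(classifierLogits(classifier, dataset)),
          ties.method = "first") - 1L
}

# forward keeping every layer output (Grad-CAM needs mid-stack activations)
nnForwardAll <- function(layers, X) {
  outs <- vector("list", length(layers))
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layerForward(layers[[i]], X)
    X <- fw$out
    outs[[i]] <- X
    caches[[i]] <- fw$cache
  }
  list(out = X, outs = outs, caches = caches)
}

# locate the activation (ReLU output) of the requested encoder conv layer
convActivationIndex <- function(encoder, convLayer = NULL) {
  convIdx <- which(vapply(encoder, function(l) l$type == "conv", TRUE))
  if (!length(convIdx)) stop("encoder has no convolutional layers")
  if (is.null(convLayer)) convLayer <- length(convIdx)
  if (convLayer < 1L || convLayer > length(convIdx))
    stop(sprintf("invalid layer identifier: %s (encoder has %d conv layers)",
                 convLayer, length(convIdx)))
  ci <- convIdx[convLayer]
  if (ci + 1L > length(encoder) || encoder[[ci + 1L]]$type != "relu")
    stop("conv layer is not followed by an activation")
  list(reluIdx = ci + 1L, outDim = encoder[[ci]]$outDim)
}

imageToColumn <- function(image) {
  if (is.matrix(image)) matrix(as.numeric(image), ncol = 1L)
  else matrix(as.numeric(image), ncol = 1L)
}

#' Grad-CAM weights: global-average-pooled gradients
#'
#' For target class \eqn{c}, computes
#' \deqn{w^c_k = \frac{1}{Z}\sum_i\sum_j
#'   \frac{\partial y^c}{\partial A^k_{ij}}, \quad Z = W\cdot H,}
#' where \eqn{y^c} is the pre-softmax class score and \eqn{A^k} the
#' forward feature maps (post-activation) of the chosen encoder conv
#' layer. Gradients come from exact backpropagation through the head and
#' the intervening encoder layers. For 3D encoders the pooling runs over
#' all voxels (\eqn{Z = D\cdot W\cdot H}).
#'
#' @param classifier a \linkS4class{ClusterClassifier}.
#' @param image a single image: \code{H x W} matrix (or \code{D x H x W}
#'   array for a 3D encoder).
#' @param targetClass 0-based class index \eqn{c}.
#' @param convLayer which encoder conv layer (1-based among conv layers);
#'   default the last.
#' @return numeric weight vector, one entry per feature map, with the
#'   forward activations attached as attribute \code{"activations"}
#'   (array, last axis = feature map).
#' @export
gradcamWeights <- function(classifier, image, targetClass,
                           convLayer = NULL) {
  if (targetClass < 0L || targetClass >= classifier@nClasses)
    stop("class index out of range")
  loc <- convActivationIndex(classifier@encoder, convLayer)
  layers <- c(classifier@encoder, classifier@head)
  x <- imageToColumn(image)
  if (nrow(x) != prod(classifier@inputShape))
    stop("image shape does not match classifier input")
  fw <- nnForwardAll(layers, x)
  C <- classifier@nClasses
  dOut <- matrix(0, C, 1L)
  dOut[targetClass + 1L, 1L] <- 1   # d y^c / d logits, pre-softmax
  bw <- nnBackward(layers, fw$caches, dOut, stopAfter = loc$reluIdx)
  od <- loc$outDim                   # (K, Do, Ho, Wo)
  K <- od[1L]; P <- prod(od[2:4])
  dA <- matrix(bw$dX, P, K)
  w <- colMeans(dA)
  A <- fw$outs[[loc$reluIdx]]
  Aarr <- if (od[2L] == 1L) array(A, c(od[3L], od[4L], K))
          else array(A, c(od[2L], od[3L], od[4L], K))
  attr(w, "activations") <- Aarr
  w
}

#' Grad-CAM map: ReLU-rectified weighted activation combination
#'
#' \deqn{I^c = ReLU\left(\sum_k w^c_k A^k\right)} elementwise over the
#' feature-map grid; entries are non-negative by construction.
#'
#' @param activations array whose last axis indexes feature maps
#'   (\code{H x W x K}, or a list of K equal-shape matrices).
#' @param weights length-K weight vector (from
#'   \code{\link{gradcamWeights}}).
#' @param targetClass optional class index recorded on the result.
#' @return a \linkS4class{Heatmap} (2D grid; for 3D activations the
#'   depth axis is preserved in attribute \code{"volume"} and the
#'   returned values grid is the depth maximum-intensity projection).
#' @export
gradcamMap <- function(activations, weights, targetClass = NA_integer_) {
  if (is.list(activations))
    activations <- simplify2array(activations)
  dims <- dim(activations)
  K <- dims[length(dims)]
  if (length(weights) != K)
    stop("shape mismatch: ", K, " feature maps but ", length(weights),
         " weights")
  flat <- matrix(activations, ncol = K)
  comb <- as.numeric(flat %*% weights)
  comb[comb < 0] <- 0
  spatial <- dims[-length(dims)]
  vol <- array(comb, spatial)
  if (length(spatial) == 2L) {
    new("Heatmap", values = vol, targetClass = as.integer(targetClass))
  } else {
    mip <- apply(vol, c(2L, 3L), max)
    hm <- new("Heatmap", values = mip, targetClass = as.integer(targetClass))
    attr(hm, "volume") <- vol
    hm
  }
}

#' Grad-CAM heatmap for one image
#'
#' Composition of \code{\link{gradcamWeights}} and
#' \code{\link{gradcamMap}}.
#'
#' @inheritParams gradcamWeights
#' @return a \linkS4class{Heatmap}.
#' @export
gradcamHeatmap <- function(classifier, image, targetClass,
                           convLayer = NULL) {
  w <- gradcamWeights(classifier, image, targetClass, convLayer)
  gradcamMap(attr(w, "activations"), as.numeric(w),
             targetClass = targetClass)
}

bilinearUpsample <- function(m, outH, outW) {
  inH <- nrow(m); inW <- ncol(m)
  rs <- if (outH > 1L) (seq_len(outH) - 1) * (inH - 1) / (outH - 1) else 0
  cs <- if (outW > 1L) (seq_len(outW) - 1) * (inW - 1) / (outW - 1) else 0
  r0 <- pmin(floor(rs), inH - 1); rf <- rs - r0
  c0 <- pmin(floor(cs), inW - 1); cf <- cs - c0
  r1 <- pmin(r0 + 1, inH - 1)
  c1 <- pmin(c0 + 1, inW - 1)
  A <- m[r0 + 1, c0 + 1, drop = FALSE]; B <- m[r0 + 1, c1 + 1, drop = FALSE]
  C <- m[r1 + 1, c0 + 1, drop = FALSE]; D <- m[r1 + 1, c1 + 1, drop = FALSE]
  wr <- matrix(rf, outH, outW); wc <- matrix(cf, outH, outW, byrow = TRUE)
  A * (1 - wr) * (1 - wc) + B * (1 - wr) * wc +
    C * wr * (1 - wc) + D * wr * wc
}

#' Otsu threshold of a [0, 1] grid
#'
#' Exhaustive 256-bin search for the threshold maximizing between-class
#' variance.
#'
#' @param x numeric values in \code{[0, 1]}.
#' @return scalar threshold.
#' @export
otsuThreshold <- function(x) {
  v <- as.numeric(x)
  nb <- 256L
  h <- tabulate(pmin(pmax(floor(v * nb) + 1L, 1L), nb), nbins = nb)
  p <- h / sum(h)
  mids <- (seq_len(nb) - 0.5) / nb
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  muT <- mu0[nb]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, nb)
  sb[ok] <- (muT * w0[ok] - mu0[ok])^2 / (w0[ok] * w1[ok])
  t <- which.max(sb)
  t / nb
}

#' Threshold a heatmap into a binary relevance mask
#'
#' The heatmap is min-max normalized to \code{[0, 1]}, bilinearly
#' upsampled to the input resolution, and thresholded — by Otsu's
#' parameter-free rule (default) or at a fixed fraction of the maximum.
#' An all-zero heatmap yields an all-false mask.
#'
#' @param hm a \linkS4class{Heatmap}.
#' @param inputShape \code{c(H, W)} target resolution.
#' @param thresholdRule \code{"otsu"} or \code{"fraction_of_max"}.
#' @param fraction threshold as fraction of the maximum, in \code{(0, 1)}
#'   (\code{fraction_of_max} only).
#' @return a \linkS4class{BinaryMask} (sourceClass inherited from the
#'   heatmap's target class).
#' @export
heatmapToMask <- function(hm, inputShape,
                          thresholdRule = c("otsu", "fraction_of_max"),
                          fraction = 0.5) {
  thresholdRule <- match.arg(thresholdRule)
  if (thresholdRule == "fraction_of_max" &&
      (fraction <= 0 || fraction >= 1))
    stop("fraction must be in (0, 1)")
  v <- hm@values
  if (!length(v)) stop("empty heatmap")
  H <- inputShape[1L]; W <- inputShape[2L]
  if (max(v) <= min(v)) {
    return(new("BinaryMask", pixels = matrix(FALSE, H, W),
               sourceClass = hm@targetClass))
  }
  norm <- (v - min(v)) / (max(v) - min(v))
  up <- bilinearUpsample(norm, H, W)
  thr <- if (thresholdRule == "otsu") otsuThreshold(up) else fraction
  new("BinaryMask", pixels = up >= thr, sourceClass = hm@targetClass)
}

#' Grad-CAM masks for every cell of a dataset
#'
#' For each cell, computes the heatmap targeted at that cell's cluster
#' label and thresholds it to a binary mask.
#'
#' @param classifier a \linkS4class{ClusterClassifier}.
#' @param dataset the \linkS4class{CellDataset}.
#' @param clusterLabels 0-based cluster label per cell.
#' @param thresholdRule,fraction passed to \code{\link{heatmapToMask}}.
#' @param convLayer passed to \code{\link{gradcamWeights}}.
#' @return list of \linkS4class{BinaryMask}.
#' @export
computeClusterMasks <- function(classifier, dataset, clusterLabels,
                                thresholdRule = "otsu", fraction = 0.5,
                                convLayer = NULL) {
  n <- nCells(dataset)
  stopifnot(length(clusterLabels) == n)
  mod <- if (classifier@inputShape[1L] == 1L) "2d" else "3d"
  shape <- classifier@inputShape
  outShape <- shape[c(2L, 3L)]
  lapply(seq_len(n), function(i) {
    img <- if (mod == "2d") dataset@images[i, , ]
           else dataset@volumes[i, , , ]
    hm <- gradcamHeatmap(classifier, img, as.integer(clusterLabels[i]),
                         convLayer)
    heatmapToMask(hm, outShape, thresholdRule, fraction)
  })
}

maskCnnLayers <- function(H, W, C = 2L) {
  l1 <- layerConv(c(1L, 1L, H, W), 8L, c(1L, 3L, 3L), c(1L, 1L, 1L))
  p1 <- layerMaxPool(c(8L, 1L, H, W))
  l2 <- layerConv(c(8L, 1L, H %/% 2L, W %/% 2L), 16L, c(1L, 3L, 3L),
                  c(1L, 1L, 1L))
  p2 <- layerMaxPool(c(16L, 1L, H %/% 2L, W %/% 2L))
  fc <- layerFC(16L * (H %/% 4L) * (W %/% 4L), C)
  list(l1, layerReLU(), p1, l2, layerReLU(), p2, fc)
}

#' Fivefold cross-validated classification of binary masks
#'
#' Quantifies whether the Grad-CAM masks carry cluster-specific patterns:
#' masks are split into five stratified folds; for each fold a small CNN
#' (conv(8)-pool-conv(16)-pool-FC, cross-entropy) is trained on the other
#' four and evaluated on the held-out fold. Reports accuracy, macro
#' precision/recall/F1 and AUC (from the class-1 softmax score) per fold.
#'
#' @param masks list of \linkS4class{BinaryMask}.
#' @param labels optional 0/1 labels; defaults to each mask's
#'   \code{sourceClass}.
#' @param seed RNG seed (fold assignment, CNN init, shuffling).
#' @param epochs,lr CNN training settings.
#' @return list with \code{folds} (per-fold metric lists), and
#'   \code{meanAccuracy}, \code{meanPrecision}, \code{meanRecall},
#'   \code{meanF1}, \code{meanAUC}.
#' @export
fiveFoldMaskCV <- function(masks, labels = NULL, seed = 1L,
                           epochs = 20L, lr = 2e-3) {
  if (is.null(labels))
    labels <- vapply(masks, function(m) m@sourceClass, 0L)
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two mask classes")
  if (any(table(labels) < 5L)) stop("need >= 5 masks per class")
  H <- nrow(masks[[1L]]@pixels); W <- ncol(masks[[1L]]@pixels)
  X <- vapply(masks, function(m) as.numeric(m@pixels), numeric(H * W))
  y <- match(labels, classes) - 1L
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in classes) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(1:5, length(idx)))
  }
  folds <- vector("list", 5L)
  for (f in 1:5) {
    test <- which(fold == f); train <- which(fold != f)
    if (length(unique(y[test])) < 2L)
      stop("class absent from a fold")
    layers <- maskCnnLayers(H, W, length(classes))
    res <- trainSoftmaxNet(layers, X[, train, drop = FALSE], y[train],
                           epochs, lr)
    logits <- nnForward(res$layers, X[, test, drop = FALSE])$out
    P <- softmaxCols(logits)
    pred <- max.col(t(logits), ties.method = "first") - 1L
    cm <- table(factor(y[test], levels = seq_along(classes) - 1L),
                factor(pred, levels = seq_along(classes) - 1L))
    cm <- matrix(as.integer(cm), nrow = nrow(cm), dimnames = dimnames(cm))
    repr <- suppressWarnings(classificationReport(cm))
    auc <- if (length(classes) == 2L)
      as.numeric(pROC::auc(pROC::roc(
        response = factor(y[test], levels = c(0L, 1L)),
        predictor = P[2L, ], levels = c("0", "1"), direction = "<",
        quiet = TRUE)))
    else NA_real_
    folds[[f]] <- list(fold = f, accuracy = repr$accuracy,
                       precision = repr$precision, recall = repr$recall,
                       f1 = repr$f1, auc = auc)
  }
  list(folds = folds, foldAssignment = fold,
       meanAccuracy = mean(vapply(folds, `[[`, 0, "accuracy")),
       meanPrecision = mean(vapply(folds, `[[`, 0, "precision")),
       meanRecall = mean(vapply(folds, `[[`, 0, "recall")),
       meanF1 = mean(vapply(folds, `[[`, 0, "f1")),
       meanAUC = mean(vapply(folds, `[[`, 0, "auc")))
}
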