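# Deep convolutional autoencoders (2D, 3D, fused) and their training.

#' Mini-batch averaged mean-square reconstruction error
#'
#' The DCAE training objective: the per-image MSE over the flattened image
#' vector (length M), averaged over the N images of the mini-batch,
#' \deqn{L = \frac{1}{N}\sum_{j=1}^{N}\frac{1}{M}\sum_{i=1}^{M}
#'   (x_{i,j} - \hat x_{i,j})^2.}
#'
#' @param batchX,batchXhat numeric arrays/matrices of identical shape; the
#'   first representation axis may be the batch axis of a stack or the
#'   column axis of a features-by-N matrix — only elementwise agreement
#'   matters.
#' @return non-negative scalar; zero iff the batches are identical.
#' @export
mseLoss <- function(batchX, batchXhat) {
  if (!identical(dim(batchX), dim(batchXhat)) ||
      length(batchX) != length(batchXhat))
    stop("shape mismatch between input and reconstruction")
  mean((batchX - batchXhat)^2)
}

#' Weighted fused reconstruction loss
#'
#' Training objective of the fused dual-modality DCAE:
#' \deqn{L = w_1 L_{MSE,2d} + (1 - w_1) L_{MSE,3d}.}
#' At \code{w1 = 1} (resp. \code{0}) it reduces exactly to the
#' single-modality loss.
#'
#' @param batch2d,batch2dHat 2D transmission batch and reconstruction.
#' @param batch3d,batch3dHat 3D SSC batch and reconstruction.
#' @param w1 modality weight in \code{[0, 1]}.
#' @return non-negative scalar.
#' @export
fusedLoss <- function(batch2d, batch2dHat, batch3d, batch3dHat, w1 = 0.5) {
  if (w1 < 0 || w1 > 1) stop("w1 must be in [0, 1]")
  w1 * mseLoss(batch2d, batch2dHat) + (1 - w1) * mseLoss(batch3d, batch3dHat)
}

#' DCAE build/training configuration
#'
#' Defaults: three stride-2 convolutional layers with channels
#' \code{(16, 32, 64)}, kernel 3, ReLU activations, a linear
#' fully-connected latent of dimension 32 per modality, mirrored
#' transposed-convolution decoder with sigmoid output, Adam at
#' \code{lr = 1e-3}, 50 epochs, batch 32. All randomness (initialization,
#' batch shuffling) flows from \code{seed}.
#'
#' @param modality \code{"2d"}, \code{"3d"} or \code{"fused"}.
#' @param convChannels encoder widths; the decoder mirrors them.
#' @param kernelSize odd convolution kernel size.
#' @param stride stride of each conv layer.
#' @param latentDim latent dimension n (per modality for fused).
#' @param w1 fused-loss weight for the 2D modality (fused only).
#' @param batchSize,epochs,learningRate Adam mini-batch settings.
#' @param inputShape2d \code{c(H, W)} of 2D inputs.
#' @param inputShape3d \code{c(D, H, W)} of 3D inputs.
#' @param seed integer RNG seed.
#' @return a \code{DCAEConfig} list.
#' @export
dcaeConfig <- function(modality = c("3d", "2d", "fused"),
                       convChannels = c(16L, 32L, 64L),
                       kernelSize = 3L, stride = 2L, latentDim = 32L,
                       w1 = 0.5, batchSize = 32L, epochs = 50L,
                       learningRate = 1e-3,
                       inputShape2d = c(80L, 80L),
                       inputShape3d = c(80L, 80L, 80L),
                       seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(latentDim >= 1L, batchSize >= 1L, epochs >= 1L,
            learningRate > 0, kernelSize %% 2L == 1L,
            length(convChannels) >= 1L)
  if (w1 < 0 || w1 > 1) stop("w1 must be in [0, 1]")
  structure(list(modality = modality,
                 convChannels = as.integer(convChannels),
                 kernelSize = as.integer(kernelSize),
                 stride = as.integer(stride),
                 latentDim = as.integer(latentDim), w1 = w1,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 learningRate = learningRate,
                 inputShape2d = as.integer(inputShape2d),
                 inputShape3d = as.integer(inputShape3d),
                 seed = as.integer(seed)),
            class = "DCAEConfig")
}

# encoder: conv/ReLU stack + linear FC to the latent; decoder mirrored.
# shape = c(D, H, W) with D = 1 for 2D inputs.
buildSingleNet <- function(shape, cfg) {
  k3 <- if (shape[1L] == 1L) c(1L, cfg$kernelSize, cfg$kernelSize)
        else rep(cfg$kernelSize, 3L)
  s3 <- if (shape[1L] == 1L) c(1L, cfg$stride, cfg$stride)
        else rep(cfg$stride, 3L)
  enc <- list()
  inDim <- c(1L, shape)
  for (i in seq_along(cfg$convChannels)) {
    l <- tryCatch(layerConv(inDim, cfg$convChannels[i], k3, s3),
                  error = function(e)
                    stop(sprintf("conv layer %d: %s", i, conditionMessage(e)),
                         call. = FALSE))
    enc <- c(enc, list(l, layerReLU()))
    inDim <- l$outDim
  }
  bottleneck <- inDim
  enc <- c(enc, list(layerFC(prod(bottleneck), cfg$latentDim)))
  dec <- list(layerFC(cfg$latentDim, prod(bottleneck)), layerReLU())
  revCh <- rev(cfg$convChannels)
  inDim <- bottleneck
  for (i in seq_along(revCh)) {
    Co <- if (i < length(revCh)) revCh[i + 1L] else 1L
    l <- layerConvT(inDim, Co, k3, s3)
    dec <- c(dec, list(l))
    if (i < length(revCh)) dec <- c(dec, list(layerReLU()))
    inDim <- l$outDim
  }
  dec <- c(dec, list(layerSigmoid()))
  list(enc = enc, dec = dec, bottleneck = bottleneck)
}

#' Build a DCAE model
#'
#' Constructs encoder and decoder stacks per the configuration and
#' initializes parameters reproducibly from \code{config$seed} (He-scaled
#' normal draws). The 3D variant uses volumetric convolutions; the fused
#' variant builds the 2D sub-model first, then the 3D sub-model.
#'
#' @param config a \code{\link{dcaeConfig}}.
#' @return an untrained \linkS4class{DCAEModel}.
#' @export
buildDCAE <- function(config) {
  stopifnot(inherits(config, "DCAEConfig"))
  set.seed(config$seed)
  net <- switch(config$modality,
    "2d" = buildSingleNet(c(1L, config$inputShape2d), config),
    "3d" = buildSingleNet(config$inputShape3d, config),
    "fused" = list(m2d = buildSingleNet(c(1L, config$inputShape2d), config),
                   m3d = buildSingleNet(config$inputShape3d, config)))
  new("DCAEModel", modality = config$modality, net = net,
      config = unclass(config), trained = FALSE)
}

# dataset -> features x N matrix for one modality
datasetTensor <- function(dataset, modality) {
  if (modality == "2d") {
    a <- dataset@images
    if (is.null(a)) stop("modality mismatch: dataset has no 2D images")
    n <- dim(a)[1L]
    matrix(aperm(a, c(2L, 3L, 1L)), ncol = n)
  } else {
    a <- dataset@volumes
    if (is.null(a)) stop("modality mismatch: dataset has no 3D volumes")
    n <- dim(a)[1L]
    matrix(aperm(a, c(2L, 3L, 4L, 1L)), ncol = n)
  }
}

trainSingle <- function(net, X, cfg, epochs) {
  layers <- c(net$enc, net$dec)
  nEnc <- length(net$enc)
  state <- adamInit(layers)
  n <- ncol(X); M <- nrow(X)
  history <- numeric(epochs)
  t <- 0L
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = cfg$batchSize)) {
      idx <- perm[start:min(start + cfg$batchSize - 1L, n)]
      xb <- X[, idx, drop = FALSE]
      fw <- nnForward(layers, xb)
      diff <- fw$out - xb
      loss <- mean(diff^2)
      if (!is.finite(loss))
        stop(sprintf("NaN loss at epoch %d", ep))
      dOut <- 2 * diff / length(diff)
      bw <- nnBackward(layers, fw$caches, dOut)
      t <- t + 1L
      upd <- adamStep(layers, bw$grads, state, cfg$learningRate, t)
      layers <- upd$layers; state <- upd$state
      tot <- tot + loss * length(idx)
    }
    history[ep] <- tot / n
  }
  net$enc <- layers[seq_len(nEnc)]
  net$dec <- layers[(nEnc + 1L):length(layers)]
  list(net = net, history = history)
}

#' Train a DCAE by mini-batch gradient descent on reconstruction error
#'
#' End-to-end Adam training on the mini-batch averaged MSE
#' (\code{\link{mseLoss}}); the fused model optimizes the
#' \code{w1}-weighted sum of the two per-modality losses
#' (\code{\link{fusedLoss}}), with both sub-models updated from the same
#' shuffled mini-batches so cell pairing is preserved. Training is
#' reproducible for a fixed \code{config$seed}.
#'
#' @param model an (untrained or trained) \linkS4class{DCAEModel}.
#' @param dataset a preprocessed \linkS4class{CellDataset} whose modality
#'   matches the model (paired data for fused).
#' @param epochs optional override of \code{config$epochs}.
#' @return the trained model, with \code{lossHistory} filled (per-epoch
#'   mean loss over the dataset).
#' @export
trainDCAE <- function(model, dataset, epochs = NULL) {
  cfg <- model@config
  if (nCells(dataset) < 1L) stop("dataset is empty")
  if (!dataset@preprocessed)
    warning("dataset not marked preprocessed; expected intensities in [0,1]")
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  set.seed(cfg$seed + 1L)
  if (model@modality != "fused") {
    X <- datasetTensor(dataset, model@modality)
    res <- trainSingle(model@net, X, cfg, epochs)
    model@net <- res$net
    model@lossHistory <- res$history
  } else {
    X2 <- datasetTensor(dataset, "2d")
    X3 <- datasetTensor(dataset, "3d")
    l2 <- c(model@net$m2d$enc, model@net$m2d$dec)
    l3 <- c(model@net$m3d$enc, model@net$m3d$dec)
    n2e <- length(model@net$m2d$enc); n3e <- length(model@net$m3d$enc)
    s2 <- adamInit(l2); s3 <- adamInit(l3)
    n <- ncol(X2)
    history <- numeric(epochs)
    w1 <- cfg$w1
    t <- 0L
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = cfg$batchSize)) {
        idx <- perm[start:min(start + cfg$batchSize - 1L, n)]
        xb2 <- X2[, idx, drop = FALSE]; xb3 <- X3[, idx, drop = FALSE]
        f2 <- nnForward(l2, xb2); f3 <- nnForward(l3, xb3)
        d2 <- f2$out - xb2; d3 <- f3$out - xb3
        loss <- w1 * mean(d2^2) + (1 - w1) * mean(d3^2)
        if (!is.finite(loss)) stop(sprintf("NaN loss at epoch %d", ep))
        b2 <- nnBackward(l2, f2$caches, 2 * w1 * d2 / length(d2))
        b3 <- nnBackward(l3, f3$caches, 2 * (1 - w1) * d3 / length(d3))
        t <- t + 1L
        u2 <- adamStep(l2, b2$grads, s2, cfg$learningRate, t)
        l2 <- u2$layers; s2 <- u2$state
        u3 <- adamStep(l3, b3$grads, s3, cfg$learningRate, t)
        l3 <- u3$layers; s3 <- u3$state
        tot <- tot + loss * length(idx)
      }
      history[ep] <- tot / n
    }
    model@net$m2d$enc <- l2[seq_len(n2e)]
    model@net$m2d$dec <- l2[(n2e + 1L):length(l2)]
    model@net$m3d$enc <- l3[seq_len(n3e)]
    model@net$m3d$dec <- l3[(n3e + 1L):length(l3)]
    model@lossHistory <- history
  }
  model@trained <- TRUE
  model
}

encodeBatched <- function(enc, X, batch = 64L) {
  starts <- seq(1L, ncol(X), by = batch)
  do.call(cbind, lapply(starts, function(s) {
    idx <- s:min(s + batch - 1L, ncol(X))
    nnForward(enc, X[, idx, drop = FALSE])$out
  }))
}

#' Encode a dataset into latent codes
#'
#' Runs the encoder(s) over every cell and returns a cells-by-n matrix of
#' latent codes. For the fused model the two encoders' codes are
#' concatenated in fixed (2d, 3d) order, giving \code{n2d + n3d} columns.
#'
#' @param model a \linkS4class{DCAEModel}.
#' @param dataset a \linkS4class{CellDataset} with matching modality.
#' @return numeric matrix, one row per cell.
#' @export
encodeCells <- function(model, dataset) {
  if (model@modality == "fused") {
    z2 <- t(encodeBatched(model@net$m2d$enc, datasetTensor(dataset, "2d")))
    z3 <- t(encodeBatched(model@net$m3d$enc, datasetTensor(dataset, "3d")))
    cbind(z2, z3)
  } else {
    t(encodeBatched(model@net$enc, datasetTensor(dataset, model@modality)))
  }
}

# flat parameter vector, used by freeze/transfer contracts
paramVector <- function(layers)
  unlist(lapply(layers, function(l) c(as.numeric(l$W), as.numeric(l$b))))

#' Save / load a DCAE model checkpoint
#'
#' The checkpoint embeds the build configuration and loss history.
#'
#' @param model a \linkS4class{DCAEModel}.
#' @param path checkpoint file path.
#' @return \code{saveDCAEModel}: \code{path} invisibly;
#'   \code{loadDCAEModel}: the model.
#' @export
saveDCAEModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveDCAEModel
#' @export
loadDCAEModel <- function(path) {
  m <- readRDS(path)
  stopifnot(is(m, "DCAEModel"))
  m
}
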