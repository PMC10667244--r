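# Internal neural-network engine for the DCAE/DCAEC models.
#
# Tensors: a batch is a plain double matrix (features x N). Per sample the
# feature vector is an R array of dim c(D, H, W, C) flattened column-major
# (depth fastest, channel slowest); 2D images are depth-1 volumes, so one
# engine serves both modalities. Convolutions require every strided spatial
# dim to be divisible by the stride (kernel odd, "same" padding), which
# makes transposed convolutions exact mirrors.
#
# Layers are plain lists; parameter updates use Adam. Everything is double
# precision and seeded through R's RNG, so training is bit-reproducible.

layerConv <- function(inDim, Co, k, stride) {
  # inDim = c(Ci, D, H, W); k, stride length-3
  spatial <- inDim[2:4]
  if (any(spatial %% stride != 0))
    stop(sprintf(
      "incompatible shape/stride: input %s not divisible by stride %s",
      paste(spatial, collapse = "x"), paste(stride, collapse = "x")))
  pad <- (k - 1L) %/% 2L
  outDim <- c(Co, spatial %/% stride)
  K <- inDim[1L] * prod(k)
  list(type = "conv",
       W = matrix(rnorm(Co * K, sd = sqrt(2 / K)), Co, K),
       b = numeric(Co),
       inDim = as.integer(inDim), outDim = as.integer(outDim),
       k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}

layerConvT <- function(inDim, Co, k, stride) {
  # inDim = c(Ci, d, h, w) (small side); output = c(Co, d*s, h*s, w*s)
  Ci <- inDim[1L]
  outDim <- c(Co, inDim[2:4] * stride)
  pad <- (k - 1L) %/% 2L
  K <- Co * prod(k)
  list(type = "convt",
       W = matrix(rnorm(Ci * K, sd = sqrt(2 / (Ci * prod(k)))), Ci, K),
       b = numeric(Co),
       inDim = as.integer(inDim), outDim = as.integer(outDim),
       k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}

layerFC <- function(nIn, nOut, act = "linear") {
  list(type = "fc",
       W = matrix(rnorm(nOut * nIn, sd = sqrt(2 / nIn)), nOut, nIn),
       b = numeric(nOut), nIn = as.integer(nIn), nOut = as.integer(nOut))
}

layerReLU <- function() list(type = "relu")
layerSigmoid <- function() list(type = "sigmoid")

layerMaxPool <- function(inDim) {
  # 2x2 max pooling over (H, W); depth must be 1
  stopifnot(inDim[2L] == 1L, inDim[3L] %% 2L == 0L, inDim[4L] %% 2L == 0L)
  list(type = "maxpool", inDim = as.integer(inDim),
       outDim = as.integer(c(inDim[1L], 1L, inDim[3:4] %/% 2L)))
}

nLayerParams <- function(layers)
  sum(vapply(layers, function(l)
    if (!is.null(l$W)) length(l$W) + length(l$b) else 0L, 0))

layerForward <- function(l, X) {
  switch(l$type,
    conv = {
      out <- cpp_conv_fwd(X, l$W, l$b, l$inDim, l$k, l$stride, l$pad, TRUE)
      list(out = out, cache = X)
    },
    convt = {
      out <- cpp_conv_bwd_data(X, l$W, l$outDim, l$k, l$stride, l$pad)
      P <- prod(l$outDim[2:4])
      out <- out + rep(l$b, each = P)
      list(out = out, cache = X)
    },
    fc = {
      list(out = (l$W %*% X) + l$b, cache = X)
    },
    relu = {
      out <- X * (X > 0)
      list(out = out, cache = (X > 0))
    },
    sigmoid = {
      out <- 1 / (1 + exp(-X))
      list(out = out, cache = out)
    },
    maxpool = {
      C <- l$inDim[1L]; H <- l$inDim[3L]; W <- l$inDim[4L]; N <- ncol(X)
      b <- array(X, c(2L, H %/% 2L, 2L, W %/% 2L, C, N))
      s1 <- b[1L, , 1L, , , , drop = FALSE]
      s2 <- b[2L, , 1L, , , , drop = FALSE]
      s3 <- b[1L, , 2L, , , , drop = FALSE]
      s4 <- b[2L, , 2L, , , , drop = FALSE]
      m <- pmax(s1, s2, s3, s4)
      out <- matrix(m, ncol = N)
      list(out = out, cache = list(b = b, m = m, N = N))
    },
    stop("unknown layer type: ", l$type))
}

layerBackward <- function(l, dOut, cache) {
  switch(l$type,
    conv = {
      dX <- cpp_conv_bwd_data(dOut, l$W, l$inDim, l$k, l$stride, l$pad)
      pg <- cpp_conv_bwd_param(cache, dOut, nrow(l$W), l$inDim, l$k,
                               l$stride, l$pad)
      list(dX = dX, grad = list(W = pg$dW, b = as.numeric(pg$db)))
    },
    convt = {
      Co <- l$outDim[1L]; P <- prod(l$outDim[2:4])
      dX <- cpp_conv_fwd(dOut, l$W, numeric(nrow(l$W)), l$outDim, l$k,
                         l$stride, l$pad, FALSE)
      pg <- cpp_conv_bwd_param(dOut, cache, nrow(l$W), l$outDim, l$k,
                               l$stride, l$pad)
      db <- colSums(matrix(rowSums(dOut), P, Co))
      list(dX = dX, grad = list(W = pg$dW, b = db))
    },
    fc = {
      list(dX = crossprod(l$W, dOut),
           grad = list(W = tcrossprod(dOut, cache), b = rowSums(dOut)))
    },
    relu = list(dX = dOut * cache, grad = NULL),
    sigmoid = list(dX = dOut * cache * (1 - cache), grad = NULL),
    maxpool = {
      b <- cache$b; m <- cache$m; N <- cache$N
      dm <- array(dOut, dim(m))
      s <- list(b[1L, , 1L, , , , drop = FALSE],
                b[2L, , 1L, , , , drop = FALSE],
                b[1L, , 2L, , , , drop = FALSE],
                b[2L, , 2L, , , , drop = FALSE])
      claimed <- array(FALSE, dim(m))
      db <- array(0, dim(b))
      sel <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
      for (q in 1:4) {
        hit <- (s[[q]] == m) & !claimed
        claimed <- claimed | hit
        db[sel[[q]][1L], , sel[[q]][2L], , , ] <- dm * hit
      }
      list(dX = matrix(db, ncol = N), grad = NULL)
    },
    stop("unknown layer type: ", l$type))
}

nnForward <- function(layers, X) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layerForward(layers[[i]], X)
    X <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = X, caches = caches)
}

# Backprop dOut through layers. Returns parameter grads and the gradient
# at the input; if stopAfter is given, returns instead the gradient with
# respect to the *output* of layer `stopAfter` (used by Grad-CAM).
nnBackward <- function(layers, caches, dOut, stopAfter = 0L) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    if (i == stopAfter) break
    bw <- layerBackward(layers[[i]], dOut, caches[[i]])
    dOut <- bw$dX
    grads[i] <- list(bw$grad)
  }
  list(dX = dOut, grads = grads)
}

adamInit <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adamStep <- function(layers, grads, state, lr, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    layers[[i]]$W <- layers[[i]]$W - lr * (st$mW / c1) /
      (sqrt(st$vW / c2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (st$mb / c1) /
      (sqrt(st$vb / c2) + eps)
    state[[i]] <- st
  }
  list(layers = layers, state = state)
}
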