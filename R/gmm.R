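# Clustering step of the DCAEC model: the trained encoder is transferred
# (decoder inactivated, parameters frozen) and the latent codes are
# clustered with a Gaussian mixture model initialized from k-means.

#' GMM clustering configuration
#'
#' @param K number of mixture components (the expected number of cell
#'   populations; K is user-supplied, no model selection is performed).
#' @param covarianceForm \code{"full"} or \code{"diagonal"}.
#' @param kmeansRestarts k-means restarts; the run with minimal
#'   within-cluster sum of squares seeds the EM.
#' @param maxIter,tol EM iteration cap and log-likelihood convergence
#'   threshold.
#' @param reg ridge added to covariance diagonals every M-step; guards
#'   against the covariance collapse that is common on easily separated
#'   latent codes.
#' @param seed RNG seed (k-means restarts).
#' @return a \code{GMMConfig} list.
#' @export
gmmConfig <- function(K, covarianceForm = c("full", "diagonal"),
                      kmeansRestarts = 10L, maxIter = 200L, tol = 1e-6,
                      reg = 1e-6, seed = 1L) {
  covarianceForm <- match.arg(covarianceForm)
  stopifnot(K >= 1L, kmeansRestarts >= 1L, maxIter >= 1L, tol > 0, reg >= 0)
  structure(list(K = as.integer(K), covarianceForm = covarianceForm,
                 kmeansRestarts = as.integer(kmeansRestarts),
                 maxIter = as.integer(maxIter), tol = tol, reg = reg,
                 seed = as.integer(seed)),
            class = "GMMConfig")
}

#' Transfer the trained encoder into the clustering model
#'
#' Returns an encoder whose parameters are bit-identical to the source
#' model's and which carries no decoder; the decoder is inactivated and the
#' encoder is frozen from here on. For the fused model both encoders are
#' transferred and their codes are concatenated in fixed (2d, 3d) order.
#'
#' @param trained a trained \linkS4class{DCAEModel}.
#' @return an encoder object accepted by \code{\link{encodeCells}}.
#' @export
transferEncoder <- function(trained) {
  stopifnot(is(trained, "DCAEModel"))
  if (!trained@trained)
    stop("model is untrained; train the DCAE before transferring")
  if (trained@modality == "fused")
    structure(list(modality = "fused",
                   enc2d = trained@net$m2d$enc,
                   enc3d = trained@net$m3d$enc),
              class = "dcaeEncoder")
  else
    structure(list(modality = trained@modality, enc = trained@net$enc),
              class = "dcaeEncoder")
}

#' Encode with a transferred encoder
#'
#' @param encoder object from \code{\link{transferEncoder}}.
#' @param dataset a \linkS4class{CellDataset}.
#' @return cells-by-n latent matrix (concatenated for fused).
#' @export
encodeWithEncoder <- function(encoder, dataset) {
  stopifnot(inherits(encoder, "dcaeEncoder"))
  if (encoder$modality == "fused") {
    z2 <- t(encodeBatched(encoder$enc2d, datasetTensor(dataset, "2d")))
    z3 <- t(encodeBatched(encoder$enc3d, datasetTensor(dataset, "3d")))
    cbind(z2, z3)
  } else {
    t(encodeBatched(encoder$enc, datasetTensor(dataset, encoder$modality)))
  }
}

#' Flat parameter vector of a model, encoder or classifier
#'
#' Used by the freeze/transfer contracts: transferred encoders must be
#' bit-identical to their source, and classifier fine-tuning must leave the
#' encoder untouched.
#'
#' @param x a \linkS4class{DCAEModel}, transferred encoder,
#'   \linkS4class{ClusterClassifier}, or raw layer list.
#' @return numeric vector of all weights and biases.
#' @export
modelParameters <- function(x) {
  if (is(x, "DCAEModel")) {
    if (x@modality == "fused")
      return(c(paramVector(x@net$m2d$enc), paramVector(x@net$m2d$dec),
               paramVector(x@net$m3d$enc), paramVector(x@net$m3d$dec)))
    return(c(paramVector(x@net$enc), paramVector(x@net$dec)))
  }
  if (inherits(x, "dcaeEncoder")) {
    if (x$modality == "fused")
      return(c(paramVector(x$enc2d), paramVector(x$enc3d)))
    return(paramVector(x$enc))
  }
  if (is(x, "ClusterClassifier"))
    return(c(paramVector(x@encoder), paramVector(x@head)))
  if (is.list(x)) return(paramVector(x))
  stop("unsupported object")
}

logGaussian <- function(Z, mean, covChol) {
  # log N(z; mean, S) with covChol = chol(S), Z cells x n
  n <- ncol(Z)
  ctr <- sweep(Z, 2L, mean)
  q <- backsolve(covChol, t(ctr), transpose = TRUE)  # solves t(R) x = t(ctr)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(covChol))) + colSums(q^2))
}

mstepCov <- function(Z, mu, r, Nk, form, reg) {
  ctr <- sweep(Z, 2L, mu)
  if (form == "full") {
    S <- crossprod(ctr * sqrt(r), ctr * sqrt(r)) / Nk
    S <- (S + t(S)) / 2
    diag(S) <- diag(S) + reg
    S
  } else {
    v <- colSums(ctr^2 * r) / Nk + reg
    diag(v, ncol(Z))
  }
}

#' Fit a Gaussian mixture to latent codes by EM with k-means initialization
#'
#' Initialization takes the best (minimal within-cluster sum of squares) of
#' \code{kmeansRestarts} k-means runs; component means start at the
#' centroids, covariances at the within-cluster covariance, weights at the
#' cluster fractions. EM then alternates responsibilities (E) and
#' maximum-likelihood parameter updates (M) with a small ridge on
#' covariance diagonals; the log-likelihood history is non-decreasing.
#' Labels are argmax responsibilities with ties broken by lowest component
#' index. Deterministic under \code{config$seed}.
#'
#' @param latent cells-by-n numeric matrix of latent codes.
#' @param config a \code{\link{gmmConfig}}.
#' @return a \linkS4class{ClusterResult}.
#' @export
fitGMM <- function(latent, config) {
  stopifnot(inherits(config, "GMMConfig"))
  Z <- as.matrix(latent)
  nc <- nrow(Z); n <- ncol(Z); K <- config$K
  if (any(!is.finite(Z))) stop("non-finite latent codes")
  if (nc < K) stop(sprintf("cells < K: %d cells for %d components", nc, K))
  if (all(apply(Z, 2L, stats::var) < 1e-24)) {
    warning("all latent codes identical; covariance regularized")
  }
  set.seed(config$seed)
  # jitter duplicated points would break kmeans with K distinct centers;
  # fall back to sampling distinct rows as centers if kmeans errors
  best <- NULL
  for (r in seq_len(config$kmeansRestarts)) {
    km <- tryCatch(
      stats::kmeans(Z, centers = K, iter.max = 100L, nstart = 1L),
      error = function(e) NULL)
    if (is.null(km)) {
      ctrIdx <- sample.int(nc, K)
      km <- list(cluster = apply(as.matrix(stats::dist(Z))[, ctrIdx,
                                                           drop = FALSE],
                                 1L, which.min),
                 centers = Z[ctrIdx, , drop = FALSE],
                 tot.withinss = Inf)
    }
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  mu <- matrix(best$centers, K, n)
  w <- as.numeric(table(factor(best$cluster, levels = seq_len(K)))) / nc
  w <- pmax(w, 1e-10); w <- w / sum(w)
  covs <- lapply(seq_len(K), function(k) {
    members <- Z[best$cluster == k, , drop = FALSE]
    S <- if (nrow(members) >= 2L) stats::cov(members) else stats::cov(Z)
    if (config$covarianceForm == "diagonal") S <- diag(diag(S), n)
    S <- (S + t(S)) / 2
    diag(S) <- diag(S) + config$reg
    S
  })
  llHist <- numeric(0)
  R <- matrix(0, nc, K)
  for (iter in seq_len(config$maxIter)) {
    logd <- vapply(seq_len(K), function(k)
      log(w[k]) + logGaussian(Z, mu[k, ], chol(covs[[k]])), numeric(nc))
    m <- apply(logd, 1L, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    R <- exp(logd - lse)
    llHist <- c(llHist, ll)
    if (iter > 1L && abs(ll - llHist[iter - 1L]) < config$tol) break
    Nk <- pmax(colSums(R), 1e-10)
    w <- Nk / nc
    mu <- crossprod(R, Z) / Nk  # K x n
    covs <- lapply(seq_len(K), function(k)
      mstepCov(Z, mu[k, ], R[, k], Nk[k], config$covarianceForm,
               config$reg))
  }
  labels <- max.col(R, ties.method = "first") - 1L
  new("ClusterResult",
      predictedLabels = as.integer(labels),
      responsibilities = R / rowSums(R),
      gmmParams = list(means = mu, covariances = covs, weights = w,
                       covarianceForm = config$covarianceForm),
      logLikHistory = llHist)
}

#' Cluster a dataset with the DCAEC model
#'
#' The composition that defines DCAEC: transfer the trained encoder,
#' encode every cell into the latent space (concatenating codes for the
#' fused model), and cluster the codes with
#' \code{\link{fitGMM}}.
#'
#' @param trained a trained \linkS4class{DCAEModel}.
#' @param dataset a preprocessed \linkS4class{CellDataset}.
#' @param config a \code{\link{gmmConfig}}.
#' @return a \linkS4class{ClusterResult}.
#' @export
clusterDataset <- function(trained, dataset, config) {
  enc <- transferEncoder(trained)
  Z <- encodeWithEncoder(enc, dataset)
  fitGMM(Z, config)
}

#' Export cluster labels as CSV
#'
#' @param result a \linkS4class{ClusterResult}.
#' @param dataset the clustered \linkS4class{CellDataset} (for cell ids).
#' @param path output CSV path (\code{cell_id,cluster}).
#' @export
writeClusterLabels <- function(result, dataset, path) {
  write.csv(data.frame(cell_id = manifest(dataset)$cell_id,
                       cluster = predictedLabels(result)),
            path, row.names = FALSE)
  invisible(path)
}
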