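setClassUnion("arrayOrNULL", c("array", "NULL"))
setClassUnion("integerOrNULL", c("integer", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' CellDataset: a stack of single-cell images, one or two modalities
#'
#' Container for per-cell image data from imaging flow cytometry (or the
#' synthetic generator). 2D transmission images are stored as an
#' \code{n x H x W} array, 3D side-scattering volumes as an
#' \code{n x D x H x W} array; when both are present they are paired by cell
#' index (cell \code{i} in one modality is cell \code{i} in the other).
#' Ground-truth labels, when available, are used only for post-evaluation.
#'
#' @slot images 2D image stack, array \code{(n, H, W)}, or \code{NULL}.
#' @slot volumes 3D volume stack, array \code{(n, D, H, W)}, or \code{NULL}.
#' @slot truthLabels optional integer vector, one label per cell.
#' @slot manifest per-cell metadata (\code{data.frame} with a
#'   \code{cell_id} column).
#' @slot pixelSizeUm physical pixel pitch of the 2D images, micrometers.
#' @slot voxelSizeUm physical voxel pitch of the 3D volumes, micrometers.
#' @slot preprocessed logical; \code{TRUE} once intensities were normalized
#'   to \code{[0, 1]}.
#' @export
setClass("CellDataset",
  representation(
    images = "arrayOrNULL",
    volumes = "arrayOrNULL",
    truthLabels = "integerOrNULL",
    manifest = "data.frame",
    pixelSizeUm = "numeric",
    voxelSizeUm = "numeric",
    preprocessed = "logical"
  ),
  prototype(
    images = NULL, volumes = NULL, truthLabels = NULL,
    manifest = data.frame(), pixelSizeUm = 0.25, voxelSizeUm = 0.25,
    preprocessed = FALSE
  )
)

setValidity("CellDataset", function(object) {
  msgs <- character()
  n2 <- if (is.null(object@images)) NA_integer_ else dim(object@images)[1L]
  n3 <- if (is.null(object@volumes)) NA_integer_ else dim(object@volumes)[1L]
  if (is.null(object@images) && is.null(object@volumes))
    msgs <- c(msgs, "dataset must contain at least one modality")
  if (!is.null(object@images) && length(dim(object@images)) != 3L)
    msgs <- c(msgs, "images must be an (n, H, W) array")
  if (!is.null(object@volumes) && length(dim(object@volumes)) != 4L)
    msgs <- c(msgs, "volumes must be an (n, D, H, W) array")
  if (!is.na(n2) && !is.na(n3) && n2 != n3)
    msgs <- c(msgs, "paired modalities must have identical cell counts")
  n <- if (!is.na(n2)) n2 else n3
  if (!is.null(object@truthLabels) && length(object@truthLabels) != n)
    msgs <- c(msgs, sprintf(
      "label count mismatch: %d labels for %d cells",
      length(object@truthLabels), n))
  if (!is.null(object@images) && any(!is.finite(object@images)))
    msgs <- c(msgs, "non-finite intensities in 2D images")
  if (!is.null(object@volumes) && any(!is.finite(object@volumes)))
    msgs <- c(msgs, "non-finite intensities in 3D volumes")
  if (isTRUE(object@preprocessed)) {
    rng <- range(c(
      if (!is.null(object@images)) range(object@images),
      if (!is.null(object@volumes)) range(object@volumes)))
    if (rng[1] < 0 || rng[2] > 1)
      msgs <- c(msgs, "preprocessed intensities must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' DCAEModel: a deep convolutional autoencoder (2D, 3D, or fused)
#'
#' Holds the encoder/decoder layer stacks, the build configuration and the
#' training loss history. For the fused model, \code{net} carries one
#' sub-model per modality (\code{m2d}, \code{m3d}) whose latent codes are
#' concatenated in fixed (2d, 3d) order at encoding time.
#'
#' @slot modality one of \code{"2d"}, \code{"3d"}, \code{"fused"}.
#' @slot net layer stacks: for single modalities \code{list(enc=, dec=)};
#'   for fused \code{list(m2d=list(enc=, dec=), m3d=list(enc=, dec=))}.
#' @slot config the \code{\link{dcaeConfig}} list the model was built from.
#' @slot lossHistory per-epoch mean reconstruction loss.
#' @slot trained logical.
#' @export
setClass("DCAEModel",
  representation(
    modality = "character",
    net = "list",
    config = "list",
    lossHistory = "numeric",
    trained = "logical"
  ),
  prototype(lossHistory = numeric(0), trained = FALSE)
)

setValidity("DCAEModel", function(object) {
  if (!object@modality %in% c("2d", "3d", "fused"))
    return("modality must be one of '2d', '3d', 'fused'")
  if (object@modality == "fused" &&
      !all(c("m2d", "m3d") %in% names(object@net)))
    return("fused model must contain sub-models m2d and m3d")
  if (object@modality != "fused" &&
      !all(c("enc", "dec") %in% names(object@net)))
    return("model must contain encoder and decoder stacks")
  TRUE
})

#' ClusterResult: output of GMM clustering on latent codes
#'
#' @slot predictedLabels integer cluster label per cell, in \code{0..K-1}
#'   (argmax responsibility, ties broken by lowest component index).
#' @slot responsibilities cells-by-K row-stochastic posterior matrix.
#' @slot gmmParams list with \code{means} (K x n), \code{covariances}
#'   (list of K matrices), \code{weights} (length K), \code{covarianceForm}.
#' @slot logLikHistory per-EM-iteration total log-likelihood
#'   (non-decreasing).
#' @export
setClass("ClusterResult",
  representation(
    predictedLabels = "integer",
    responsibilities = "matrix",
    gmmParams = "list",
    logLikHistory = "numeric"
  )
)

setValidity("ClusterResult", function(object) {
  msgs <- character()
  rs <- rowSums(object@responsibilities)
  if (any(abs(rs - 1) > 1e-9))
    msgs <- c(msgs, "responsibility rows must sum to 1")
  w <- object@gmmParams$weights
  if (!is.null(w) && abs(sum(w) - 1) > 1e-9)
    msgs <- c(msgs, "mixing weights must sum to 1")
  if (length(object@predictedLabels) != nrow(object@responsibilities))
    msgs <- c(msgs, "one label per cell required")
  if (length(msgs)) msgs else TRUE
})

#' ClusterClassifier: frozen encoder plus a fine-tuned two-layer head
#'
#' CNN classifier used by the Grad-CAM interpretation stage: the encoder is
#' transferred from a trained DCAE and frozen; only the two fully connected
#' head layers are trained (cross-entropy on cluster labels).
#'
#' @slot encoder frozen encoder layer stack.
#' @slot head two fully connected layers producing pre-softmax logits.
#' @slot nClasses number of cluster classes.
#' @slot inputShape spatial input shape \code{(D, H, W)} (\code{D = 1} for
#'   2D models).
#' @slot history per-epoch training cross-entropy.
#' @export
setClass("ClusterClassifier",
  representation(
    encoder = "list",
    head = "list",
    nClasses = "integer",
    inputShape = "integer",
    history = "numeric"
  )
)

#' Heatmap: Grad-CAM relevance map for one image and one target class
#'
#' @slot values non-negative relevance grid at the resolution of the target
#'   convolutional layer's feature maps (ReLU output of the weighted
#'   activation combination).
#' @slot targetClass class index \code{c} whose pre-softmax score was
#'   differentiated.
#' @slot upsampled optional input-resolution (bilinear) version.
#' @export
setClass("Heatmap",
  representation(
    values = "matrix",
    targetClass = "integer",
    upsampled = "matrixOrNULL"
  ),
  prototype(upsampled = NULL)
)

setValidity("Heatmap", function(object) {
  if (any(object@values < 0)) "heatmap values must be non-negative (ReLU)"
  else TRUE
})

#' BinaryMask: thresholded relevance mask at input resolution
#'
#' @slot pixels logical matrix; \code{TRUE} marks high-relevance pixels.
#' @slot sourceClass cluster label of the image the mask came from.
#' @export
setClass("BinaryMask",
  representation(pixels = "matrix", sourceClass = "integer")
)

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels)) "mask pixels must be logical" else TRUE
})
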