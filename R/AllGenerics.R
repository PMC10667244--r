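#' @name accessors
#' @title Accessors for DCAEC classes
#' @description Slot accessors for \linkS4class{CellDataset},
#'   \linkS4class{DCAEModel} and \linkS4class{ClusterResult}. Use these
#'   rather than \code{@} access.
#' @param x an object of the documented class.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("images2d", function(x) standardGeneric("images2d"))
#' @rdname accessors
#' @export
setGeneric("volumes3d", function(x) standardGeneric("volumes3d"))
#' @rdname accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))
#' @rdname accessors
#' @export
setGeneric("predictedLabels", function(x) standardGeneric("predictedLabels"))
#' @rdname accessors
#' @export
setGeneric("responsibilities", function(x) standardGeneric("responsibilities"))
#' @rdname accessors
#' @export
setGeneric("gmmParams", function(x) standardGeneric("gmmParams"))
#' @rdname accessors
#' @export
setGeneric("logLikHistory", function(x) standardGeneric("logLikHistory"))

#' @rdname accessors
#' @export
setMethod("nCells", "CellDataset", function(x) {
  if (!is.null(x@images)) dim(x@images)[1L] else dim(x@volumes)[1L]
})
#' @rdname accessors
#' @export
setMethod("images2d", "CellDataset", function(x) x@images)
#' @rdname accessors
#' @export
setMethod("volumes3d", "CellDataset", function(x) x@volumes)
#' @rdname accessors
#' @export
setMethod("truthLabels", "CellDataset", function(x) x@truthLabels)
#' @rdname accessors
#' @export
setMethod("manifest", "CellDataset", function(x) x@manifest)
#' @rdname accessors
#' @export
setMethod("modality", "CellDataset", function(x) {
  has2 <- !is.null(x@images); has3 <- !is.null(x@volumes)
  if (has2 && has3) "paired" else if (has2) "2d" else "3d"
})

#' @rdname accessors
#' @export
setMethod("modality", "DCAEModel", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("lossHistory", "DCAEModel", function(x) x@lossHistory)

#' @rdname accessors
#' @export
setMethod("predictedLabels", "ClusterResult", function(x) x@predictedLabels)
#' @rdname accessors
#' @export
setMethod("responsibilities", "ClusterResult", function(x) x@responsibilities)
#' @rdname accessors
#' @export
setMethod("gmmParams", "ClusterResult", function(x) x@gmmParams)
#' @rdname accessors
#' @export
setMethod("logLikHistory", "ClusterResult", function(x) x@logLikHistory)

setMethod("show", "CellDataset", function(object) {
  cat("CellDataset with", nCells(object), "cells\n")
  if (!is.null(object@images))
    cat("  2D transmission images:",
        paste(dim(object@images)[-1L], collapse = " x "),
        sprintf("(%.3g um/px)\n", object@pixelSizeUm))
  if (!is.null(object@volumes))
    cat("  3D SSC volumes:",
        paste(dim(object@volumes)[-1L], collapse = " x "),
        sprintf("(%.3g um/vx)\n", object@voxelSizeUm))
  if (!is.null(object@truthLabels)) {
    tb <- table(object@truthLabels)
    cat("  truth labels:", paste(sprintf("%s:%d", names(tb), tb),
                                 collapse = ", "), "\n")
  } else cat("  truth labels: absent\n")
  cat("  preprocessed:", object@preprocessed, "\n")
})

setMethod("show", "DCAEModel", function(object) {
  cat(sprintf("DCAEModel (%s)%s\n", object@modality,
              if (object@trained) ", trained" else ", untrained"))
  cfg <- object@config
  cat("  latent dim:", cfg$latentDim,
      if (object@modality == "fused") "(per modality, concatenated)" else "",
      "\n")
  if (length(object@lossHistory))
    cat(sprintf("  loss: %.5g -> %.5g over %d epochs\n",
                object@lossHistory[1],
                object@lossHistory[length(object@lossHistory)],
                length(object@lossHistory)))
})

setMethod("show", "ClusterResult", function(object) {
  K <- ncol(object@responsibilities)
  tb <- table(factor(object@predictedLabels, levels = 0:(K - 1)))
  cat(sprintf("ClusterResult: %d cells in %d clusters\n",
              length(object@predictedLabels), K))
  cat("  sizes:", paste(sprintf("%s:%d", names(tb), tb), collapse = ", "),
      "\n")
  cat(sprintf("  final log-likelihood: %.6g (%d EM iterations)\n",
              object@logLikHistory[length(object@logLikHistory)],
              length(object@logLikHistory)))
})

setMethod("show", "ClusterClassifier", function(object) {
  cat(sprintf(
    "ClusterClassifier: frozen encoder + 2 FC layers, %d classes\n",
    object@nClasses))
})
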