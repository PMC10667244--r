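# Image stack I/O and preprocessing.
#
# Axis convention (shared by every module): stacks are (cell, height, width)
# for 2D transmission images and (cell, depth, height, width) for 3D SSC
# volumes; depth is the light-sheet scan axis. The instrument-scale acquisition
# is 80x80 px (20x20 um) and 80^3 vx (20^3 um); nothing is hardcoded to
# those sizes.

#' Construct a CellDataset from in-memory arrays
#'
#' @param images optional \code{(n, H, W)} array of 2D transmission images.
#' @param volumes optional \code{(n, D, H, W)} array of 3D SSC volumes.
#' @param truthLabels optional integer vector of ground-truth labels
#'   (post-evaluation only).
#' @param manifest optional per-cell metadata; a default \code{cell_id}
#'   manifest is created when omitted.
#' @param pixelSizeUm,voxelSizeUm physical pitch in micrometers (default
#'   0.25, the 20 um / 80 px instrument scale).
#' @param preprocessed set \code{TRUE} if intensities are already in
#'   \code{[0, 1]}.
#' @return a \linkS4class{CellDataset}.
#' @export
cellDataset <- function(images = NULL, volumes = NULL, truthLabels = NULL,
                        manifest = NULL, pixelSizeUm = 0.25,
                        voxelSizeUm = 0.25, preprocessed = FALSE) {
  n <- if (!is.null(images)) dim(images)[1L]
       else if (!is.null(volumes)) dim(volumes)[1L]
       else stop("at least one modality required")
  if (is.null(manifest))
    manifest <- data.frame(cell_id = seq_len(n) - 1L)
  if (!is.null(truthLabels)) truthLabels <- as.integer(truthLabels)
  new("CellDataset", images = images, volumes = volumes,
      truthLabels = truthLabels, manifest = manifest,
      pixelSizeUm = pixelSizeUm, voxelSizeUm = voxelSizeUm,
      preprocessed = preprocessed)
}

#' Load a single-cell image stack from disk
#'
#' Reads an NPY (preferred, bit-exact) or multi-page TIFF stack and returns
#' a \linkS4class{CellDataset}. NPY stacks must have shape \code{(n, H, W)}
#' for \code{modality = "2d"} or \code{(n, D, H, W)} for \code{"3d"};
#' multi-page TIFF supplies one page per cell (2D only). Raw intensities are
#' preserved — call \code{\link{preprocess}} before training.
#'
#' @param path path to \code{.npy} or \code{.tif}/\code{.tiff} stack.
#' @param modality \code{"2d"} or \code{"3d"}.
#' @param labelsPath optional one-column-per-field CSV
#'   (\code{cell_id,label}) of ground-truth labels.
#' @param pixelSizeUm physical pitch, micrometers.
#' @return a \linkS4class{CellDataset}.
#' @export
loadDataset <- function(path, modality = c("2d", "3d"), labelsPath = NULL,
                        pixelSizeUm = 0.25) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "npy") {
    a <- readNpy(path)
    if (!is.numeric(a)) stop("non-numeric content in ", path)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    dims <- unique(lapply(pages, dim))
    if (length(dims) != 1L)
      stop("TIFF pages have inconsistent shapes in ", path)
    a <- aperm(simplify2array(pages), c(3L, 1L, 2L))
  } else stop("unsupported stack format: .", ext)
  need <- if (modality == "2d") 3L else 4L
  if (length(dim(a)) != need)
    stop(sprintf("shape mismatch: %s stack must have %d axes, got %d",
                 modality, need, length(dim(a))))
  labels <- NULL
  if (!is.null(labelsPath)) {
    lab <- read.csv(labelsPath)
    if (!"label" %in% names(lab))
      stop("labels CSV must contain a 'label' column")
    if (nrow(lab) != dim(a)[1L])
      stop(sprintf("label count mismatch: %d labels for %d cells",
                   nrow(lab), dim(a)[1L]))
    labels <- as.integer(lab$label)
  }
  if (modality == "2d")
    cellDataset(images = a, truthLabels = labels, pixelSizeUm = pixelSizeUm)
  else
    cellDataset(volumes = a, truthLabels = labels, voxelSizeUm = pixelSizeUm)
}

#' Save a CellDataset to disk
#'
#' Writes NPY stacks (\code{images.npy} / \code{volumes.npy}), labels as
#' \code{labels.csv} (\code{cell_id,label}) and the manifest as
#' \code{manifest.json} into \code{dir}.
#'
#' @param dataset a \linkS4class{CellDataset}.
#' @param dir output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
saveDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(dataset@images))
    writeNpy(dataset@images, file.path(dir, "images.npy"))
  if (!is.null(dataset@volumes))
    writeNpy(dataset@volumes, file.path(dir, "volumes.npy"))
  if (!is.null(dataset@truthLabels))
    write.csv(data.frame(cell_id = dataset@manifest$cell_id,
                         label = dataset@truthLabels),
              file.path(dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_cells = nCells(dataset),
         modality = modality(dataset),
         pixel_size_um = dataset@pixelSizeUm,
         voxel_size_um = dataset@voxelSizeUm,
         preprocessed = dataset@preprocessed,
         manifest = dataset@manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

minmaxOne <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi > lo) (x - lo) / (hi - lo) else array(0, dim(x))
}

#' Normalize image intensities to [0, 1]
#'
#' Per-image min-max scaling (the default) maps each cell image's minimum
#' to 0 and maximum to 1 independently, matching the scale of the MSE
#' reconstruction loss and the sigmoid decoder output. \code{minmax_global}
#' uses one min/max per modality across the whole stack. Constant images
#' map to all-zeros rather than erroring (robust to blank frames).
#'
#' @param dataset a \linkS4class{CellDataset}.
#' @param method \code{"minmax_per_image"} (default) or
#'   \code{"minmax_global"}.
#' @return the dataset with intensities in \code{[0, 1]} and
#'   \code{preprocessed = TRUE}.
#' @export
preprocess <- function(dataset,
                       method = c("minmax_per_image", "minmax_global")) {
  method <- match.arg(method)
  if (nCells(dataset) < 1L) stop("dataset is empty")
  scaleStack <- function(a) {
    if (is.null(a)) return(NULL)
    if (method == "minmax_global") return(minmaxOne(a))
    mins <- apply(a, 1L, min)
    rng <- apply(a, 1L, max) - mins
    rng[rng == 0] <- 1  # constant images land on all-zeros
    sweep(sweep(a, 1L, mins, "-"), 1L, rng, "/")
  }
  dataset@images <- scaleStack(dataset@images)
  dataset@volumes <- scaleStack(dataset@volumes)
  dataset@preprocessed <- TRUE
  validObject(dataset)
  dataset
}

#' Subset a CellDataset by cell index
#'
#' Keeps modality pairing and labels consistent.
#'
#' @param x a \linkS4class{CellDataset}.
#' @param i integer cell indices (1-based).
#' @export
setMethod("[", "CellDataset", function(x, i, j, ..., drop = FALSE) {
  img <- if (!is.null(x@images)) x@images[i, , , drop = FALSE]
  vol <- if (!is.null(x@volumes)) x@volumes[i, , , , drop = FALSE]
  lab <- if (!is.null(x@truthLabels)) x@truthLabels[i]
  cellDataset(images = img, volumes = vol, truthLabels = lab,
              manifest = x@manifest[i, , drop = FALSE],
              pixelSizeUm = x@pixelSizeUm, voxelSizeUm = x@voxelSizeUm,
              preprocessed = x@preprocessed)
})
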