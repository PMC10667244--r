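# Synthetic single-cell image generator.
#
# Emulates the qualitative class structure of label-free IFC populations:
# cell size (radius), internal granularity (SSC-like speckle texture with a
# controllable correlation length) and sub-cellular signal localization
# (nucleus vs. cytoplasm, the protein-translocation phenotype). Cells are
# spheres/discs with a concentric nucleus at half the cell radius; speckle
# is low-pass-filtered Gaussian noise inside the cell mask, rectified and
# contrast-stretched. Not a physical light-scattering simulation.

#' Specification of one synthetic cell class
#'
#' @param classId integer class label.
#' @param radiusMeanPx,radiusSdPx cell radius distribution, pixels.
#' @param speckleGrainPx correlation length of the internal speckle
#'   texture, pixels (larger = coarser granularity).
#' @param localizationFraction fraction of internal signal concentrated in
#'   the central nucleus (radius/2 ball) vs. the cytoplasmic shell, in
#'   \code{[0, 1]}. 0.5 is unlocalized; the translocation phenotype is
#'   emulated by contrasting e.g. 0.8 vs. 0.2.
#' @param intensityContrast overall intensity scale in \code{(0, 1]}.
#' @param noiseSd additive Gaussian noise sd (post-noise images are
#'   clipped to \code{[0, 1]}).
#' @return a \code{ClassSpec} list.
#' @export
classSpec <- function(classId, radiusMeanPx = 8, radiusSdPx = 0.8,
                      speckleGrainPx = 1.5, localizationFraction = 0.5,
                      intensityContrast = 0.9, noiseSd = 0.02) {
  stopifnot(radiusMeanPx > 0, radiusSdPx >= 0, speckleGrainPx > 0,
            localizationFraction >= 0, localizationFraction <= 1,
            intensityContrast > 0, noiseSd >= 0)
  structure(list(classId = as.integer(classId),
                 radiusMeanPx = radiusMeanPx, radiusSdPx = radiusSdPx,
                 speckleGrainPx = speckleGrainPx,
                 localizationFraction = localizationFraction,
                 intensityContrast = intensityContrast,
                 noiseSd = noiseSd),
            class = "ClassSpec")
}

#' Configuration for synthetic dataset generation
#'
#' Shapes default to the instrument acquisition geometry (80x80 px
#' transmission, 80^3 vx SSC); scaled-down shapes (e.g. 32^3) are the usual
#' choice for desk-scale experiments.
#'
#' @param specs list of \code{\link{classSpec}} objects.
#' @param nPerClass cells generated per class.
#' @param shape2d \code{c(H, W)} of 2D images.
#' @param shape3d \code{c(D, H, W)} of 3D volumes.
#' @param modality \code{"2d"}, \code{"3d"} or \code{"paired"} (both
#'   modalities from the same per-cell geometry).
#' @param seed integer; identical seeds give bit-identical datasets, and
#'   per-cell substreams are derived by counter so increasing
#'   \code{nPerClass} never reshuffles earlier cells.
#' @return a \code{SyntheticConfig} list.
#' @export
syntheticConfig <- function(specs, nPerClass = 100L,
                            shape2d = c(80L, 80L),
                            shape3d = c(80L, 80L, 80L),
                            modality = c("3d", "2d", "paired"),
                            seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(length(specs) >= 1L, nPerClass >= 1L,
            all(shape2d > 0), all(shape3d > 0))
  structure(list(specs = specs, nPerClass = as.integer(nPerClass),
                 shape2d = as.integer(shape2d),
                 shape3d = as.integer(shape3d),
                 modality = modality, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# separable Gaussian blur along every axis via banded-matrix GEMM
blurKernelMatrix <- function(n, sigma) {
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-d^2 / (2 * sigma^2))
  K / rowSums(K)
}

blurArray <- function(a, sigma) {
  nd <- length(dim(a))
  for (ax in seq_len(nd)) {
    d <- dim(a)
    K <- blurKernelMatrix(d[1L], sigma)
    a <- array(K %*% matrix(a, d[1L], prod(d[-1L])), d)
    a <- aperm(a, c(seq_len(nd)[-1L], 1L))  # cycle axes
  }
  a
}

radialDistance <- function(shape, center) {
  grids <- lapply(seq_along(shape), function(ax) {
    g <- (seq_len(shape[ax]) - center[ax])^2
    dimv <- rep(1L, length(shape)); dimv[ax] <- shape[ax]
    array(rep(g, each = prod(shape[seq_len(ax - 1L)])), shape)
  })
  sqrt(Reduce("+", grids))
}

cellSeedFor <- function(seed, classIdx, cellIdx) {
  (as.numeric(seed) * 7 + classIdx * 1000003 + cellIdx * 8191) %% 2147483647
}

# one cell, one modality; shape length 2 -> image, 3 -> volume
renderCell <- function(shape, spec, r, center, speckled) {
  dist <- radialDistance(shape, center)
  soft <- 1 / (1 + exp((dist - r) / 0.7))          # cell boundary
  nuc <- 1 / (1 + exp((dist - r / 2) / 0.7))       # nucleus boundary
  vNuc <- sum(nuc); vCyt <- sum(pmax(soft - nuc, 0))
  f <- spec$localizationFraction
  amp <- f / max(vNuc, 1) * nuc +
    (1 - f) / max(vCyt, 1) * pmax(soft - nuc, 0)
  amp <- amp / max(amp)
  if (speckled) {
    s <- abs(blurArray(array(rnorm(prod(shape)), shape),
                       spec$speckleGrainPx))
    s <- minmaxOne(s)
    tex <- 0.25 + 0.75 * s
  } else {
    tex <- 0.85 + 0.15 * minmaxOne(blurArray(array(rnorm(prod(shape)),
                                                   shape), 2))
  }
  img <- amp * tex * spec$intensityContrast
  img <- pmin(pmax(img, 0), 1)
  if (spec$noiseSd > 0)
    img <- pmin(pmax(img + rnorm(prod(shape), sd = spec$noiseSd), 0), 1)
  array(img, shape)
}

#' Generate a synthetic CellDataset
#'
#' Produces \code{length(specs) * nPerClass} cells with
#' \code{truthLabels} set to each spec's \code{classId}. In paired mode the
#' 2D transmission-like image (smooth disc with nucleus shading) and the 3D
#' SSC-like volume (granular speckle inside the cell mask) for a given cell
#' share the same radius and center, so the 2D boundary radius equals the
#' 3D mid-plane radius.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return a \linkS4class{CellDataset} with intensities in \code{[0, 1]}.
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  C <- length(config$specs); n <- config$nPerClass
  want2d <- config$modality %in% c("2d", "paired")
  want3d <- config$modality %in% c("3d", "paired")
  if (want2d) {
    lim <- min(config$shape2d) / 2
    bad <- vapply(config$specs, function(s) s$radiusMeanPx >= lim, TRUE)
    if (any(bad)) stop("radius exceeds half the 2D image extent")
  }
  if (want3d) {
    lim <- min(config$shape3d) / 2
    bad <- vapply(config$specs, function(s) s$radiusMeanPx >= lim, TRUE)
    if (any(bad)) stop("radius exceeds half the 3D volume extent")
  }
  total <- C * n
  imgs <- if (want2d) array(0, c(total, config$shape2d))
  vols <- if (want3d) array(0, c(total, config$shape3d))
  labels <- integer(total)
  radii <- numeric(total)
  i <- 0L
  for (ci in seq_len(C)) {
    spec <- config$specs[[ci]]
    for (j in seq_len(n)) {
      i <- i + 1L
      set.seed(cellSeedFor(config$seed, ci, j))
      r <- max(2, rnorm(1, spec$radiusMeanPx, spec$radiusSdPx))
      if (want3d) {
        # depth center stays exact so the mid-plane radius equals r
        ctr <- (config$shape3d + 1) / 2 + c(0, runif(2, -1.2, 1.2))
        vols[i, , , ] <- renderCell(config$shape3d, spec, r, ctr,
                                    speckled = TRUE)
        ctr2 <- ctr[2:3]
      } else {
        ctr2 <- (config$shape2d + 1) / 2 + runif(2, -1.2, 1.2)
      }
      if (want2d)
        imgs[i, , ] <- renderCell(config$shape2d, spec,
                                  r, ctr2, speckled = FALSE)
      labels[i] <- spec$classId
      radii[i] <- r
    }
  }
  man <- data.frame(cell_id = seq_len(total) - 1L,
                    class_id = labels, radius_px = radii)
  cellDataset(images = imgs, volumes = vols, truthLabels = labels,
              manifest = man, preprocessed = TRUE)
}

#' Reference class specifications for the bundled experiments
#'
#' Two ready-made population designs used throughout the package's examples
#' and validation runs:
#' \itemize{
#'   \item \code{wbcLikeSpecs()}: three classes differing in cell radius and
#'     internal granularity, emulating a three-part white-blood-cell-like
#'     population (small/fine, medium/medium, large/coarse) for 3D SSC
#'     clustering.
#'   \item \code{translocationLikeSpecs(f)}: two classes identical in every
#'     respect except the nucleus/cytoplasm localization fraction,
#'     emulating the protein-translocation phenotype for the fused
#'     dual-modality model. \code{f = c(0.5, 0.5)} gives the matched
#'     chance-control population.
#' }
#'
#' @param f length-2 localization fractions for the two classes.
#' @return list of \code{\link{classSpec}}.
#' @export
wbcLikeSpecs <- function() list(
  classSpec(0, radiusMeanPx = 6, radiusSdPx = 0.6, speckleGrainPx = 1.0),
  classSpec(1, radiusMeanPx = 9, radiusSdPx = 0.8, speckleGrainPx = 2.0),
  classSpec(2, radiusMeanPx = 12, radiusSdPx = 1.0, speckleGrainPx = 3.5))

#' @rdname wbcLikeSpecs
#' @export
translocationLikeSpecs <- function(f = c(0.8, 0.2)) list(
  classSpec(0, radiusMeanPx = 9, radiusSdPx = 0.8, speckleGrainPx = 2.0,
            localizationFraction = f[1L]),
  classSpec(1, radiusMeanPx = 9, radiusSdPx = 0.8, speckleGrainPx = 2.0,
            localizationFraction = f[2L]))

#' Generate labeled binary-mask fixtures
#'
#' Two mask classes with a known discriminative spatial pattern plus
#' salt noise, used to exercise and validate the cross-validated
#' mask-classification stage on a construction with a known answer.
#'
#' @param nPerClass masks per class.
#' @param shape \code{c(H, W)}.
#' @param pattern \code{"half_split"} (class 0 white on the left half,
#'   class 1 on the right) or \code{"ring_vs_blob"} (central disc vs.
#'   annulus).
#' @param noiseFlipProb per-pixel flip probability, in \code{[0, 0.5)}.
#' @param seed RNG seed.
#' @return list with \code{masks} (list of \linkS4class{BinaryMask}) and
#'   \code{labels} (integer vector of 0/1).
#' @export
generateMaskFixtures <- function(nPerClass, shape = c(32L, 32L),
                                 pattern = c("half_split", "ring_vs_blob"),
                                 noiseFlipProb = 0, seed = 1L) {
  pattern <- match.arg(pattern)
  if (noiseFlipProb < 0 || noiseFlipProb >= 0.5)
    stop("noiseFlipProb must be in [0, 0.5)")
  H <- shape[1L]; W <- shape[2L]
  base <- vector("list", 2L)
  if (pattern == "half_split") {
    m0 <- matrix(FALSE, H, W); m0[, seq_len(floor(W / 2))] <- TRUE
    m1 <- matrix(FALSE, H, W); m1[, (floor(W / 2) + 1L):W] <- TRUE
  } else {
    dist <- radialDistance(c(H, W), (c(H, W) + 1) / 2)
    m0 <- dist <= 0.28 * min(H, W)
    m1 <- dist > 0.28 * min(H, W) & dist <= 0.45 * min(H, W)
  }
  base[[1L]] <- m0; base[[2L]] <- m1
  set.seed(seed)
  masks <- vector("list", 2L * nPerClass)
  labels <- integer(2L * nPerClass)
  k <- 0L
  for (cls in 0:1) {
    for (j in seq_len(nPerClass)) {
      k <- k + 1L
      m <- base[[cls + 1L]]
      if (noiseFlipProb > 0) {
        flip <- matrix(runif(H * W) < noiseFlipProb, H, W)
        m <- xor(m, flip)
      }
      masks[[k]] <- new("BinaryMask", pixels = m,
                        sourceClass = as.integer(cls))
      labels[k] <- cls
    }
  }
  list(masks = masks, labels = labels)
}
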