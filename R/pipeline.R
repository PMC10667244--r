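# End-to-end orchestration: generate/load -> train -> cluster -> evaluate
# -> interpret, with every stage seeded from one global seed and all
# artifacts written to a run directory.

deriveSeed <- function(seed, offset) as.integer((seed + offset) %% 2147483647)

#' Read a pipeline run configuration
#'
#' YAML or JSON; the structure mirrors \code{\link{runPipeline}}'s
#' documented fields.
#'
#' @param path config file path.
#' @return config list.
#' @export
readRunConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: .", ext)
}

requireField <- function(config, field) {
  parts <- strsplit(field, ".", fixed = TRUE)[[1L]]
  x <- config
  for (p in parts) {
    if (!is.list(x) || is.null(x[[p]]))
      stop("missing config field: ", field)
    x <- x[[p]]
  }
  x
}

specsFromConfig <- function(classCfgs) {
  lapply(seq_along(classCfgs), function(i) {
    cc <- classCfgs[[i]]
    do.call(classSpec, c(list(classId = if (is.null(cc$classId)) i - 1L
                                        else cc$classId),
                         cc[setdiff(names(cc), "classId")]))
  })
}

#' Run the DCAEC pipeline
#'
#' Executes the requested stages in order and writes artifacts, a manifest
#' (config, config hash, versions) and a log into \code{outDir}. Identical
#' configurations produce byte-identical metrics files. Any stage failure
#' halts with the stage name and cause.
#'
#' Config fields: \code{seed}, \code{outDir}, \code{stages} (subset of
#' \code{generate}, \code{train}, \code{cluster}, \code{evaluate},
#' \code{interpret}), \code{synthetic} (\code{nPerClass}, \code{modality},
#' \code{shape2d}, \code{shape3d}, \code{classes} — a list of
#' \code{\link{classSpec}} argument lists), \code{dataset} (\code{path},
#' \code{modality}, \code{labelsPath}; used instead of \code{generate}),
#' \code{dcae} (\code{\link{dcaeConfig}} arguments), \code{gmm}
#' (\code{\link{gmmConfig}} arguments, notably \code{K}), and
#' \code{gradcam} (\code{epochs}, \code{hidden}, \code{thresholdRule},
#' \code{cvEpochs}).
#'
#' @param config config list or path to a YAML/JSON config.
#' @param outDir optional override of \code{config$outDir}.
#' @return the run directory, invisibly; artifacts on disk.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  if (!is.null(outDir)) config$outDir <- outDir
  outDir <- requireField(config, "outDir")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stages <- if (is.null(config$stages))
    c("generate", "train", "cluster", "evaluate") else config$stages
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "log.txt")
  logLine <- function(...) cat(sprintf("[%s] ", format(Sys.time())),
                               sprintf(...), "\n", sep = "",
                               file = logFile, append = TRUE)
  runStage <- function(name, fn) {
    logLine("stage %s: start", name)
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    logLine("stage %s: done", name)
    res
  }
  cfgJson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null")
  cfgPath <- file.path(outDir, "config.json")
  writeLines(cfgJson, cfgPath)
  manifestOut <- list(
    config_hash = unname(tools::md5sum(cfgPath)),
    package_version = as.character(utils::packageVersion("DCAEC")),
    r_version = as.character(getRversion()),
    stages = stages, seed = seed)
  jsonlite::write_json(manifestOut, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  dataset <- NULL
  if ("generate" %in% stages) {
    dataset <- runStage("generate", function() {
      sc <- requireField(config, "synthetic")
      specs <- specsFromConfig(requireField(config, "synthetic.classes"))
      gcfg <- syntheticConfig(
        specs = specs,
        nPerClass = requireField(config, "synthetic.nPerClass"),
        shape2d = if (is.null(sc$shape2d)) c(80L, 80L)
                  else as.integer(unlist(sc$shape2d)),
        shape3d = if (is.null(sc$shape3d)) c(80L, 80L, 80L)
                  else as.integer(unlist(sc$shape3d)),
        modality = if (is.null(sc$modality)) "3d" else sc$modality,
        seed = deriveSeed(seed, 0L))
      ds <- generateDataset(gcfg)
      saveDataset(ds, file.path(outDir, "dataset"))
      ds
    })
  } else if (any(c("train", "cluster", "evaluate", "interpret")
                 %in% stages)) {
    dataset <- runStage("load", function() {
      dcfg <- requireField(config, "dataset")
      path <- requireField(config, "dataset.path")
      ds <- loadDataset(path,
                        modality = if (is.null(dcfg$modality)) "3d"
                                   else dcfg$modality,
                        labelsPath = dcfg$labelsPath)
      preprocess(ds)
    })
  }

  model <- NULL
  if ("train" %in% stages) {
    model <- runStage("train", function() {
      dc <- config$dcae
      if (is.null(dc)) dc <- list()
      mod <- if (!is.null(dc$modality)) dc$modality
             else switch(modality(dataset), paired = "fused",
                         modality(dataset))
      args <- dc[setdiff(names(dc), "modality")]
      if (!is.null(dataset@images))
        args$inputShape2d <- dim(dataset@images)[-1L]
      if (!is.null(dataset@volumes))
        args$inputShape3d <- dim(dataset@volumes)[-1L]
      args$modality <- mod
      args$seed <- deriveSeed(seed, 1000L)
      mcfg <- do.call(dcaeConfig, args)
      m <- trainDCAE(buildDCAE(mcfg), dataset)
      write.csv(data.frame(epoch = seq_along(lossHistory(m)),
                           loss = lossHistory(m)),
                file.path(outDir, "loss_history.csv"), row.names = FALSE)
      saveDCAEModel(m, file.path(outDir, "dcae_model.rds"))
      m
    })
  }

  result <- NULL
  if ("cluster" %in% stages) {
    result <- runStage("cluster", function() {
      if (is.null(model)) {
        mp <- file.path(outDir, "dcae_model.rds")
        if (!file.exists(mp))
          stop("no trained model; run the train stage first")
        model <<- loadDCAEModel(mp)
      }
      K <- requireField(config, "gmm.K")
      gargs <- config$gmm
      gargs$K <- K
      gargs$seed <- deriveSeed(seed, 2000L)
      gcfg <- do.call(gmmConfig, gargs)
      res <- clusterDataset(model, dataset, gcfg)
      writeClusterLabels(res, dataset, file.path(outDir, "clusters.csv"))
      jsonlite::write_json(
        list(weights = gmmParams(res)$weights,
             means = gmmParams(res)$means,
             covariance_form = gmmParams(res)$covarianceForm,
             log_likelihood = logLikHistory(res)),
        file.path(outDir, "gmm_params.json"), digits = NA,
        auto_unbox = TRUE, matrix = "rowmajor")
      res
    })
  }

  if ("evaluate" %in% stages) {
    runStage("evaluate", function() {
      if (is.null(truthLabels(dataset)))
        stop("evaluate stage needs truth labels")
      ev <- evaluateClustering(truthLabels(dataset),
                               predictedLabels(result))
      write.csv(as.data.frame.matrix(ev$confusion),
                file.path(outDir, "confusion_matrix.csv"))
      jsonlite::write_json(
        ev[c("balancedAccuracy", "perClassAccuracy", "precision",
             "recall", "f1", "accuracy", "nClasses")],
        file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
      enc <- transferEncoder(model)
      Z <- encodeWithEncoder(enc, dataset)
      xy <- embedLatent2D(Z, seed = deriveSeed(seed, 2500L))
      write.csv(data.frame(cell_id = manifest(dataset)$cell_id, xy,
                           truth = truthLabels(dataset),
                           cluster = predictedLabels(result)),
                file.path(outDir, "embedding.csv"), row.names = FALSE)
      ev
    })
  }

  if ("interpret" %in% stages) {
    runStage("interpret", function() {
      gc <- config$gradcam
      if (is.null(gc)) gc <- list()
      cls <- trainClusterClassifier(
        model, dataset, predictedLabels(result),
        epochs = if (is.null(gc$epochs)) 50L else gc$epochs,
        hidden = if (is.null(gc$hidden)) 64L else gc$hidden,
        seed = deriveSeed(seed, 3000L))
      masks <- computeClusterMasks(
        cls, dataset, predictedLabels(result),
        thresholdRule = if (is.null(gc$thresholdRule)) "otsu"
                        else gc$thresholdRule)
      H <- nrow(masks[[1L]]@pixels); W <- ncol(masks[[1L]]@pixels)
      stack <- array(0, c(length(masks), H, W))
      for (i in seq_along(masks)) stack[i, , ] <- masks[[i]]@pixels + 0
      writeNpy(stack, file.path(outDir, "masks.npy"))
      cv <- fiveFoldMaskCV(masks,
                           labels = predictedLabels(result),
                           seed = deriveSeed(seed, 4000L),
                           epochs = if (is.null(gc$cvEpochs)) 20L
                                    else gc$cvEpochs)
      df <- do.call(rbind, lapply(cv$folds, as.data.frame))
      names(df) <- c("Fold", "Accuracy", "Precision", "Recall", "F1",
                     "AUC")
      write.csv(df, file.path(outDir, "mask_cv_metrics.csv"),
                row.names = FALSE)
      cv
    })
  }
  invisible(outDir)
}

#' Plot the 2D latent embedding colored by label
#'
#' @param coords cells-by-2 matrix from \code{\link{embedLatent2D}}.
#' @param labels integer labels used for coloring.
#' @param file PNG output path.
#' @export
plotLatentEmbedding <- function(coords, labels, file) {
  grDevices::png(file, width = 800, height = 800, res = 120)
  on.exit(grDevices::dev.off())
  cols <- grDevices::hcl.colors(max(3L, length(unique(labels))), "Dark 3")
  graphics::plot(coords[, 1L], coords[, 2L],
                 col = cols[as.integer(factor(labels))], pch = 19,
                 cex = 0.7, xlab = "dim 1", ylab = "dim 2",
                 main = "latent space (2D projection)")
  invisible(file)
}

#' Input / heatmap / overlay panel for one cell
#'
#' @param image H-by-W input image.
#' @param hm a \linkS4class{Heatmap}.
#' @param file PNG output path.
#' @export
plotGradcamOverlay <- function(image, hm, file) {
  up <- bilinearUpsample(
    if (max(hm@values) > min(hm@values))
      (hm@values - min(hm@values)) / (max(hm@values) - min(hm@values))
    else hm@values * 0,
    nrow(image), ncol(image))
  grDevices::png(file, width = 1200, height = 420, res = 120)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  showIm <- function(m, main, col = grDevices::gray.colors(256, 0, 1)) {
    graphics::image(t(m[nrow(m):1, ]), axes = FALSE, col = col,
                    main = main, useRaster = TRUE)
  }
  showIm(image, "input")
  showIm(up, "Grad-CAM", col = grDevices::hcl.colors(256, "Inferno"))
  graphics::image(t(image[nrow(image):1, ]), axes = FALSE,
                  col = grDevices::gray.colors(256, 0, 1),
                  main = "overlay", useRaster = TRUE)
  graphics::image(t(up[nrow(up):1, ]), axes = FALSE,
                  col = grDevices::hcl.colors(256, "Inferno", alpha = 0.45),
                  add = TRUE, useRaster = TRUE)
  invisible(file)
}
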