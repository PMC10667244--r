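# Shared fixtures. Heavier objects (trained tiny models) are built once per
# session and memoized, so individual test files stay cheap.

fixtureCache <- new.env(parent = emptyenv())

memoize <- function(key, fn) {
  if (is.null(fixtureCache[[key]])) fixtureCache[[key]] <- fn()
  fixtureCache[[key]]
}

tinySpecs2 <- function() list(
  classSpec(0, radiusMeanPx = 4, radiusSdPx = 0.4, speckleGrainPx = 1.0),
  classSpec(1, radiusMeanPx = 6.5, radiusSdPx = 0.5, speckleGrainPx = 2.5))

# 2 classes x 12 cells of 16^3 volumes, for fast training-path tests
tinyDataset3d <- function(seed = 3L, nPerClass = 12L)
  generateDataset(syntheticConfig(tinySpecs2(), nPerClass,
                                  shape3d = c(16L, 16L, 16L),
                                  modality = "3d", seed = seed))

tinyDatasetPaired <- function(seed = 3L, nPerClass = 10L)
  generateDataset(syntheticConfig(tinySpecs2(), nPerClass,
                                  shape2d = c(16L, 16L),
                                  shape3d = c(16L, 16L, 16L),
                                  modality = "paired", seed = seed))

tinyConfig3d <- function(seed = 3L, epochs = 4L)
  dcaeConfig("3d", convChannels = c(4L, 8L), latentDim = 8L,
             epochs = epochs, batchSize = 16L,
             inputShape3d = c(16L, 16L, 16L), seed = seed)

tinyConfig2d <- function(seed = 3L, epochs = 4L)
  dcaeConfig("2d", convChannels = c(4L, 8L), latentDim = 8L,
             epochs = epochs, batchSize = 16L,
             inputShape2d = c(16L, 16L), seed = seed)

tinyTrained3d <- function() memoize("trained3d", function()
  trainDCAE(buildDCAE(tinyConfig3d()), tinyDataset3d()))

# paired 2-class dataset with a localization phenotype + trained fused model
tinyTrainedFused <- function() memoize("trainedFused", function() {
  specs <- list(
    classSpec(0, radiusMeanPx = 5, radiusSdPx = 0.4, speckleGrainPx = 1.5,
              localizationFraction = 0.85),
    classSpec(1, radiusMeanPx = 5, radiusSdPx = 0.4, speckleGrainPx = 1.5,
              localizationFraction = 0.15))
  ds <- generateDataset(syntheticConfig(specs, 20L, shape2d = c(16L, 16L),
                                        shape3d = c(16L, 16L, 16L),
                                        modality = "paired", seed = 5L))
  cfg <- dcaeConfig("fused", convChannels = c(4L, 8L), latentDim = 8L,
                    epochs = 4L, batchSize = 16L,
                    inputShape2d = c(16L, 16L),
                    inputShape3d = c(16L, 16L, 16L), seed = 5L)
  list(ds = ds, model = trainDCAE(buildDCAE(cfg), ds))
})

expect_rel_equal <- function(x, y, tol = 1e-10) {
  expect_lt(max(abs(x - y)) / max(1e-300, max(abs(y))), tol)
}
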