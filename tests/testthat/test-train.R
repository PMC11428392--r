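test_that("training memorizes a tiny fixed dataset", {
  cfg <- syntheticConfig(nImages = 5, frame = c(64L, 64L), seed = 3)
  ds <- sampleHandDataset(cfg)
  aug <- augmentConfig(resizeTo = c(64L, 64L), translatePx = c(0, 0),
                       rotateRad = c(0, 0), elasticAmpPx = 0,
                       intensityShift = c(0, 0), intensityScale = c(0, 0),
                       occlusionEnabled = FALSE)
  ucfg <- unetConfig(levels = 3L, width = 16L, dropout = 0)
  tr <- trainLocalizerFast(ds$images, ds$landmarks, ucfg,
                           trainConfig(epochs = 200L, batch = 5L, lr = 5e-3,
                                       seed = 1L),
                           aug, blobConfig(), head = "none")
  expect_equal(nrow(tr$history), 200L)
  expect_lt(tail(tr$history$heatmapLoss, 1), tr$history$heatmapLoss[1])
  preds <- predictLandmarks(tr$model, ds$images)
  errs <- unlist(lapply(1:5, function(m)
    pointError(preds[[m]], landmarkCoords(ds$landmarks[[m]]), 1)))
  expect_lt(mean(errs), 3)
  expect_lt(median(errs), 2)
})

test_that("the single-precision engine reproduces the reference training", {
  set.seed(1)
  frame <- c(32L, 32L)
  cfg <- syntheticConfig(nImages = 8, frame = frame, seed = 5, jitterSd = 0.3,
                         translatePx = 2, rotation = 0.05)
  ds <- sampleHandDataset(cfg)
  aug <- augmentConfig(resizeTo = frame, translatePx = c(-1, 1),
                       rotateRad = c(-0.05, 0.05), elasticAmpPx = 1)
  ucfg <- unetConfig(levels = 2L, width = 4L, dropout = 0, finalKernel = 1L)
  tcfg <- trainConfig(epochs = 2L, batch = 4L, lr = 1e-3, seed = 3L)
  topo <- defaultHandTopology()
  bank <- buildPriorBank(ds$landmarks, topo, frame, augCfg = NULL,
                         cfg = gmmFitConfig(maxComponents = 1L, seed = 2L),
                         gridStep = 8L)
  ga <- gaffaInit(bank, topo, frame,
                  gaffaConfig(downFactor = 4L, kernelStoreFactor = 2L))
  ref <- trainLocalizer(ds$images, ds$landmarks, ucfg, tcfg, aug,
                        blobConfig(), head = "gaffa", ga = ga)
  fast <- trainLocalizerFast(ds$images, ds$landmarks, ucfg, tcfg, aug,
                             blobConfig(), head = "gaffa", ga = ga)
  expect_equal(fast$history$heatmapLoss, ref$history$heatmapLoss,
               tolerance = 1e-4)
  expect_equal(fast$history$coordLoss, ref$history$coordLoss,
               tolerance = 1e-4)
  expect_equal(fast$lambda, ref$lambda, tolerance = 1e-4)
  expect_equal(fast$model$params$enc1_c1$w, ref$model$params$enc1_c1$w,
               tolerance = 1e-3)
  # both lambdas were fixed at the first batch and never updated
  expect_length(fast$lambda, 1)
})

test_that("joint training balances the two losses once at the first batch", {
  frame <- c(32L, 32L)
  cfg <- syntheticConfig(nImages = 4, frame = frame, seed = 6, jitterSd = 0.3,
                         translatePx = 2, rotation = 0.05)
  ds <- sampleHandDataset(cfg)
  aug <- augmentConfig(resizeTo = frame, translatePx = c(0, 0),
                       rotateRad = c(0, 0), elasticAmpPx = 0,
                       occlusionEnabled = FALSE)
  topo <- defaultHandTopology()
  bank <- buildPriorBank(ds$landmarks, topo, frame, augCfg = NULL,
                         cfg = gmmFitConfig(maxComponents = 1L, seed = 2L),
                         gridStep = 8L)
  ga <- gaffaInit(bank, topo, frame,
                  gaffaConfig(downFactor = 4L, kernelStoreFactor = 2L))
  tr <- trainLocalizer(ds$images, ds$landmarks,
                       unetConfig(levels = 2L, width = 3L, dropout = 0,
                                  finalKernel = 1L),
                       trainConfig(epochs = 2L, batch = 4L, seed = 5L),
                       aug, blobConfig(), head = "gaffa", ga = ga)
  # lambda equals the first-batch loss ratio: recompute that batch
  expect_true(is.finite(tr$lambda))
  expect_gt(tr$lambda, 0)
})
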