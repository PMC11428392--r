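# Scaled-down synthetic end-to-end study: trains the localizer with and
# without the sum-product refinement head on generated hand images and
# evaluates both under the standard and the occlusion test protocols.

#' Configuration of the synthetic end-to-end study
#'
#' Defines the full scaled study: a 60-image synthetic hand dataset at
#' 128 x 128 (fold 1 of the three-fold split: 40 training, 20 test images),
#' a compact localizer (3 levels, 8 channels, no dropout),
#' spatial/intensity/occlusion-box augmentation with ranges scaled to the
#' frame, mixture priors fitted from three augmented draws per training
#' image, and the refinement layer at working resolution 16 (kernels stored
#' at 16, upsampled to 32). Training runs a fixed epoch count at batch 8
#' with Adam. Both models (with and without the refinement head) share
#' every other setting.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param epochs training epochs for both models (the default runs the
#'   study at a size that completes in roughly a quarter hour on one CPU;
#'   see the methods vignette for the study-size discussion).
#' @param nImages synthetic dataset size.
#' @param frameSize square frame edge in px.
#' @param width,levels localizer capacity.
#' @param lr Adam learning rate.
#' @param batch batch size.
#' @param downFactor,kernelStoreFactor refinement working resolution.
#' @param occlusionRuns runs of the occlusion protocol per model.
#' @param fingerSelectProb per-finger selection probability in the protocol.
#' @return a config list.
#' @export
studyConfig <- function(seed = 1L, epochs = 60L, nImages = 60L,
                        frameSize = 128L, width = 8L, levels = 3L,
                        lr = 2e-3, batch = 8L, downFactor = 8L,
                        kernelStoreFactor = 2L, occlusionRuns = 10L,
                        fingerSelectProb = 0.2) {
  list(seed = as.integer(seed), epochs = as.integer(epochs),
       nImages = as.integer(nImages), frameSize = as.integer(frameSize),
       width = as.integer(width), levels = as.integer(levels), lr = lr,
       batch = as.integer(batch), downFactor = as.integer(downFactor),
       kernelStoreFactor = as.integer(kernelStoreFactor),
       occlusionRuns = as.integer(occlusionRuns),
       fingerSelectProb = fingerSelectProb)
}

#' Run the synthetic end-to-end study
#'
#' Generates the dataset, fits the conditional prior bank on the training
#' split, trains the localizer once alone and once end-to-end with the
#' refinement head (identical seeds, augmentation stream and epochs), and
#' evaluates both on the held-out split: standard test metrics (point errors
#' in px, with the wrist pair giving approximately 1 mm/px) and the
#' occlusion protocol with finger circle-chains.
#'
#' @param cfg a [studyConfig()].
#' @param verbose epoch print interval (0 = silent).
#' @return list with `unet` and `gaffa` sublists (each: `standard` and
#'   `occlusion` [MetricsSummary-class], `meanTestPePx`), plus the trained
#'   objects and the dataset.
#' @export
runSyntheticStudy <- function(cfg = studyConfig(), verbose = 0) {
  frame <- c(cfg$frameSize, cfg$frameSize)
  scaleAug <- cfg$frameSize / 256
  synCfg <- syntheticConfig(nImages = cfg$nImages, frame = frame,
                            seed = deriveSeed(cfg$seed, 101))
  ds <- sampleHandDataset(synCfg)
  tr <- ds$folds[[1]]$train; te <- ds$folds[[1]]$test
  augCfg <- augmentConfig(resizeTo = frame,
                          translatePx = c(-10, 10) * scaleAug,
                          elasticAmpPx = 20 * scaleAug)
  blobCfg <- blobConfig()
  unetCfg <- unetConfig(levels = cfg$levels, width = cfg$width, dropout = 0)
  trainCfg <- trainConfig(epochs = cfg$epochs, batch = cfg$batch, lr = cfg$lr,
                          seed = deriveSeed(cfg$seed, 202))
  topo <- defaultHandTopology()
  gaCfg <- gaffaConfig(downFactor = cfg$downFactor,
                       kernelStoreFactor = cfg$kernelStoreFactor)
  bank <- buildPriorBank(ds$landmarks[tr], topo, frame, augCfg = augCfg,
                         cfg = gmmFitConfig(maxComponents = 3L,
                                            samplesPerImage = 3L,
                                            seed = deriveSeed(cfg$seed, 303)),
                         gridStep = cfg$downFactor * cfg$kernelStoreFactor)
  ga0 <- gaffaInit(bank, topo, frame, gaCfg)
  joint <- trainLocalizerFast(ds$images[tr], ds$landmarks[tr], unetCfg,
                              trainCfg, augCfg, blobCfg, head = "gaffa",
                              ga = ga0, verbose = verbose)
  alone <- trainLocalizerFast(ds$images[tr], ds$landmarks[tr], unetCfg,
                              trainCfg, augCfg, blobCfg, head = "none",
                              verbose = verbose)
  predGaffa <- function(img) predictLandmarks(joint$model, list(img),
                                              ga = joint$ga)[[1]]
  predUnet <- function(img) predictLandmarks(alone$model, list(img))[[1]]
  teImgs <- ds$images[te]; teLms <- ds$landmarks[te]
  scales <- vapply(teLms, normalizationConstant, numeric(1))
  occCfg <- occlusionTestConfig(fingerSelectProb = cfg$fingerSelectProb,
                                circleRadiusPx = 10,
                                runsPerFold = cfg$occlusionRuns,
                                seed = deriveSeed(cfg$seed, 404))
  # px-scale metrics: radii in px (the wrist pair makes 1 px about 1 mm)
  pxRadii <- c(2, 4, 10)
  res <- list()
  for (nm in c("gaffa", "unet")) {
    pred <- if (nm == "gaffa") predGaffa else predUnet
    std <- evaluateStandard(pred, teImgs, teLms, radiiMm = pxRadii,
                            scales = rep(1, length(teImgs)))
    occ <- runOcclusionEval(pred, teImgs, teLms, occCfg,
                            radiiMm = pxRadii, scales = rep(1, length(teImgs)))
    res[[nm]] <- list(standard = std, occlusion = occ,
                      meanTestPePx = std@meanMm)
  }
  res$joint <- joint; res$alone <- alone; res$bank <- bank
  res$dataset <- list(train = tr, test = te, frame = frame)
  res$scalesMmPerPx <- scales
  res
}
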