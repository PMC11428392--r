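# End-to-end training of the localization U-Net, optionally with the
# differentiable sum-product refinement head or the SCN head attached.

#' Training configuration
#'
#' @param epochs fixed epoch count, no early stopping (reference: 800).
#' @param batch batch size (reference: 8).
#' @param lr Adam learning rate (reference: 1e-3).
#' @param seed RNG seed controlling initialization, shuffling, augmentation
#'   and dropout.
#' @return a config list.
#' @export
trainConfig <- function(epochs = 800L, batch = 8L, lr = 1e-3, seed = 1L) {
  stopifnot(epochs >= 1, batch >= 1, lr > 0)
  list(epochs = as.integer(epochs), batch = as.integer(batch), lr = lr,
       seed = as.integer(seed))
}

# Assemble one augmented batch: images [H,W,1,B], targets [H,W,L,B],
# coordinate targets [L,2,B], visibility L x B.
makeBatch <- function(images, landmarks, idx, augCfg, blobCfg, frame,
                      occlude = TRUE) {
  B <- length(idx); L <- length(landmarks[[1]])
  x <- array(0, c(frame[1], frame[2], 1, B))
  tgt <- array(0, c(frame[1], frame[2], L, B))
  coords <- array(0, c(L, 2, B))
  vis <- matrix(FALSE, L, B)
  for (b in seq_len(B)) {
    k <- idx[b]
    st <- spatialTransform(images[[k]], landmarks[[k]], augCfg)
    img <- intensityTransform(st$image, augCfg)
    x[, , 1, b] <- img
    lm <- st$landmarks
    vis[, b] <- landmarkVisible(lm)
    co <- landmarkCoords(lm)
    co[!vis[, b], ] <- 0
    coords[, , b] <- co
    tgt <- cpp_render_targets_slab(tgt, co, vis[, b], b, blobCfg$sigma,
                                   blobCfg$gamma, blobCfg$family == "gaussian")
  }
  if (occlude && augCfg$occlusionEnabled) {
    batchImgs <- array(x[, , 1, ], c(frame[1], frame[2], B))
    x[, , 1, ] <- occlusionBoxes(batchImgs, augCfg)$batch
  }
  list(x = x, tgt = tgt, coords = coords, vis = vis)
}

#' Train the localizer, optionally end-to-end with a refinement head
#'
#' Runs the fixed-epoch Adam loop over augmented batches with the
#' visibility-masked heatmap MSE. With `head = "gaffa"` the refined
#' coordinates additionally contribute a coordinate MSE whose weight is set
#' once from the loss magnitudes of the first batch
#' (`lambda = heatmap loss / coordinate loss`) and never updated, and the
#' conditional kernels, biases and heatmap batch normalization are trained
#' jointly with the U-Net. With `head = "scn"` the heatmap MSE is evaluated
#' on the product output only.
#'
#' @param images,landmarks training images (H x W matrices, all sharing the
#'   frame) and matching [LandmarkSet-class] annotations.
#' @param unetCfg a [unetConfig()].
#' @param trainCfg a [trainConfig()].
#' @param augCfg an [augmentConfig()] (its `resizeTo` must equal the frame).
#' @param blobCfg a [blobConfig()] for the regression targets.
#' @param head "none", "gaffa" or "scn".
#' @param ga state from [gaffaInit()] (required for `head = "gaffa"`).
#' @param scn model from [scnInit()] (required for `head = "scn"`).
#' @param freezePriors if TRUE the conditional kernels stay at their
#'   initialization (ablation switch); biases and batch norm still train.
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @return list(model, ga, scn, history, lambda).
#' @export
trainLocalizer <- function(images, landmarks, unetCfg = unetConfig(),
                           trainCfg = trainConfig(), augCfg = augmentConfig(),
                           blobCfg = blobConfig(),
                           head = c("none", "gaffa", "scn"),
                           ga = NULL, scn = NULL, freezePriors = FALSE,
                           verbose = 0) {
  head <- match.arg(head)
  if (head == "gaffa" && is.null(ga)) stop("head = 'gaffa' needs a prepared state (gaffaInit)")
  if (head == "scn" && is.null(scn)) stop("head = 'scn' needs an SCN model (scnInit)")
  frame <- dim(images[[1]])
  model <- unetInit(unetCfg, seed = trainCfg$seed)
  optU <- adamInit(model$params)
  optG <- if (head == "gaffa") adamInit(ga$params) else NULL
  optS <- if (head == "scn") adamInit(scn$params) else NULL
  n <- length(images)
  lambda <- NA_real_
  history <- data.frame(epoch = integer(0), heatmapLoss = numeric(0),
                        coordLoss = numeric(0))
  for (epoch in seq_len(trainCfg$epochs)) {
    set.seed(deriveSeed(trainCfg$seed, epoch))
    ord <- sample.int(n)
    nb <- ceiling(n / trainCfg$batch)
    ehl <- 0; ecl <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1) * trainCfg$batch + 1):min(bi * trainCfg$batch, n)]
      batch <- makeBatch(images, landmarks, idx, augCfg, blobCfg, frame)
      fw <- unetForward(model, batch$x, training = TRUE)
      model$buffers <- fw$buffers
      if (head == "scn") {
        sf <- scnForward(scn, fw$out, training = TRUE)
        scn$buffers <- sf$buffers
        hl <- heatmapLoss(sf$out, batch$tgt, batch$vis)
        sb <- scnBackward(scn, sf$cache, hl$grad)
        gout <- sb$glocal
        stepS <- adamStep(scn$params, sb$grads, optS, lr = trainCfg$lr)
        scn$params <- stepS$params; optS <- stepS$state
        cl <- list(loss = NA_real_)
      } else {
        hl <- heatmapLoss(fw$out, batch$tgt, batch$vis)
        gout <- hl$grad
        cl <- list(loss = NA_real_)
        if (head == "gaffa") {
          gfw <- gaffaForward(ga, fw$out, training = TRUE, keepEnergies = FALSE)
          ga$buffers <- gfw$buffers
          cl <- coordinateLoss(gfw$coords, batch$coords, batch$vis)
          if (is.na(lambda))
            lambda <- hl$loss / max(cl$loss, 1e-12)
          gbw <- gaffaBackward(ga, gfw$cache, gcoords = lambda * cl$grad)
          gout <- gout + gbw$gheat
          gr <- gbw$grads
          if (freezePriors) gr$kernels <- lapply(gr$kernels, function(m) m * 0)
          stepG <- adamStep(ga$params, gr, optG, lr = trainCfg$lr)
          ga$params <- stepG$params; optG <- stepG$state
        }
      }
      bw <- unetBackward(model, fw$cache, gout)
      if (!all(vapply(flattenParams(bw$grads), function(g) all(is.finite(g)), logical(1)))) {
        dump <- file.path(tempdir(), "gaffa_diverged_state.rds")
        saveRDS(list(model = model, epoch = epoch, batch = bi), dump)
        stop("training diverged (non-finite loss/gradient) at epoch ", epoch,
             "; state dumped to ", dump)
      }
      stepU <- adamStep(model$params, bw$grads, optU, lr = trainCfg$lr)
      model$params <- stepU$params; optU <- stepU$state
      ehl <- ehl + hl$loss; ecl <- ecl + if (is.na(cl$loss)) 0 else cl$loss
    }
    history <- rbind(history, data.frame(epoch = epoch, heatmapLoss = ehl / nb,
                                         coordLoss = ecl / nb))
    if (verbose > 0 && epoch %% verbose == 0)
      message(sprintf("epoch %d/%d heatmap %.4g coord %.4g", epoch,
                      trainCfg$epochs, ehl / nb, ecl / nb))
  }
  list(model = model, ga = if (head == "gaffa") ga else NULL,
       scn = if (head == "scn") scn else NULL,
       history = history, lambda = lambda)
}

#' Predict landmark coordinates for images
#'
#' Runs the trained localizer in inference mode (running batch-norm
#' statistics, no dropout) and decodes coordinates: heatmap argmax for the
#' plain U-Net or the SCN product, soft-argmax of the marginal energies when
#' a trained refinement state is supplied.
#'
#' @param model trained U-Net.
#' @param images list of H x W matrices (intensity-normalized like training
#'   inputs; pass raw [0, 1] images and set `normalize = TRUE` to apply the
#'   same [-1, 1] rescaling used before training perturbations).
#' @param ga optional trained refinement state.
#' @param scn optional trained SCN model.
#' @param normalize rescale inputs to [-1, 1] first (default TRUE).
#' @return list of L x 2 coordinate matrices.
#' @export
predictLandmarks <- function(model, images, ga = NULL, scn = NULL,
                             normalize = TRUE) {
  lapply(images, function(img) {
    if (normalize) {
      rng <- range(img)
      img <- if (diff(rng) > 0) 2 * (img - rng[1]) / diff(rng) - 1 else img * 0
    }
    fw <- unetForward(model, img, training = FALSE)
    if (!is.null(ga)) {
      gfw <- gaffaForward(ga, fw$out, training = FALSE)
      co <- matrix(gfw$coords[, , 1], dim(fw$out)[3], 2)
    } else if (!is.null(scn)) {
      sf <- scnForward(scn, fw$out, training = FALSE)
      co <- decodeStack(array(sf$out, dim(sf$out)[1:3]), "argmax")
    } else {
      co <- decodeStack(array(fw$out, dim(fw$out)[1:3]), "argmax")
    }
    colnames(co) <- c("u", "v")
    co
  })
}

#' Standard (unoccluded) test-set evaluation
#'
#' @param predictor function(image) returning an L x 2 coordinate matrix.
#' @param images,landmarks test images and annotations.
#' @param radiiMm outlier radii.
#' @param scales per-image mm-per-pixel constants (default: wrist pair).
#' @return a [MetricsSummary-class].
#' @export
evaluateStandard <- function(predictor, images, landmarks,
                             radiiMm = c(2, 4, 10), scales = NULL) {
  if (is.null(scales))
    scales <- vapply(landmarks, normalizationConstant, numeric(1))
  errs <- c()
  for (m in seq_along(images)) {
    pred <- predictor(images[[m]])
    vis <- landmarkVisible(landmarks[[m]])
    co <- landmarkCoords(landmarks[[m]])
    errs <- c(errs, pointError(pred[vis, , drop = FALSE],
                               co[vis, , drop = FALSE], scales[[m]]))
  }
  summarizeErrors(errs, radiiMm)
}

#' Fast single-precision training path
#'
#' Drives the compiled single-precision training engine with exactly the
#' same batch assembly, augmentation stream, loss definitions and Adam
#' schedule as [trainLocalizer()] (the double-precision reference). The
#' trained weights are exported back into the standard model structures, so
#' prediction and evaluation always run through the reference code. Dropout
#' is not supported on this path.
#'
#' @inheritParams trainLocalizer
#' @return list(model, ga, history, lambda), as for [trainLocalizer()].
#' @export
trainLocalizerFast <- function(images, landmarks, unetCfg = unetConfig(),
                               trainCfg = trainConfig(), augCfg = augmentConfig(),
                               blobCfg = blobConfig(),
                               head = c("none", "gaffa"), ga = NULL,
                               verbose = 0) {
  head <- match.arg(head)
  if (unetCfg$dropout > 0)
    stop("the single-precision training engine does not support dropout")
  if (head == "gaffa" && is.null(ga)) stop("head = 'gaffa' needs a prepared state (gaffaInit)")
  frame <- dim(images[[1]])
  model <- unetInit(unetCfg, seed = trainCfg$seed)
  n <- length(images)
  B <- trainCfg$batch
  gaffaState <- if (head == "gaffa")
    list(params = ga$params, cfg = ga$cfg, pairs = ga$pairs) else NULL
  ptr <- cpp_trainer_create(model$params, unetCfg, gaffaState,
                            frame[1], frame[2], B)
  history <- data.frame(epoch = integer(0), heatmapLoss = numeric(0),
                        coordLoss = numeric(0))
  for (epoch in seq_len(trainCfg$epochs)) {
    set.seed(deriveSeed(trainCfg$seed, epoch))
    ord <- sample.int(n)
    nb <- floor(n / B)   # the engine runs fixed-size batches
    if (nb == 0) stop("need at least one full batch")
    ehl <- 0; ecl <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1) * B + 1):(bi * B)]
      batch <- makeBatch(images, landmarks, idx, augCfg, blobCfg, frame)
      r <- cpp_trainer_step(ptr, batch$x, batch$tgt, batch$coords,
                            matrix(as.numeric(batch$vis), nrow(batch$vis)),
                            trainCfg$lr, TRUE)
      if (!is.finite(r$heatmapLoss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      ehl <- ehl + r$heatmapLoss
      ecl <- ecl + if (is.na(r$coordLoss)) 0 else r$coordLoss
    }
    history <- rbind(history, data.frame(epoch = epoch, heatmapLoss = ehl / nb,
                                         coordLoss = ecl / nb))
    if (verbose > 0 && epoch %% verbose == 0)
      message(sprintf("epoch %d/%d heatmap %.4g coord %.4g", epoch,
                      trainCfg$epochs, ehl / nb, ecl / nb))
  }
  ex <- cpp_trainer_export(ptr)
  model$params <- ex$params
  model$buffers <- ex$buffers
  # re-attach dims lost over the C++ boundary
  for (nm in names(model$params))
    model$params[[nm]] <- lapply(model$params[[nm]], function(v)
      if (is.matrix(v)) v else as.numeric(v))
  outGa <- NULL
  if (head == "gaffa") {
    outGa <- ga
    outGa$params$kernels <- stats::setNames(ex$gaffaParams$kernels, ga$pairs$key)
    outGa$params$biases <- stats::setNames(ex$gaffaParams$biases, ga$pairs$key)
    outGa$params$bnGamma <- as.numeric(ex$gaffaParams$bnGamma)
    outGa$params$bnBeta <- as.numeric(ex$gaffaParams$bnBeta)
    outGa$buffers <- list(rm = as.numeric(ex$gaffaBuffers$rm),
                          rv = as.numeric(ex$gaffaBuffers$rv))
  }
  list(model = model, ga = outGa, scn = NULL, history = history,
       lambda = ex$lambda)
}
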