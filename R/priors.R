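# Conditional displacement priors p(i | j) estimated with Gaussian mixtures.

#' Gaussian-mixture fitting configuration for conditional priors
#'
#' @param maxComponents largest number of mixture components tried (default
#'   10); reduced automatically when fewer than `2 * maxComponents` samples
#'   are available.
#' @param samplesPerImage spatially augmented coordinate draws per training
#'   image (default 3), making the priors robust to the training-time
#'   spatial transformations.
#' @param ridge covariance regularization floor added to the diagonal
#'   (px^2), protecting degenerate clusters.
#' @param seed RNG seed for the fitting.
#' @return a config list.
#' @export
gmmFitConfig <- function(maxComponents = 10L, samplesPerImage = 3L,
                         ridge = 1e-3, seed = 1L) {
  stopifnot(maxComponents >= 1, samplesPerImage >= 1, ridge >= 0)
  list(maxComponents = as.integer(maxComponents),
       samplesPerImage = as.integer(samplesPerImage),
       ridge = ridge, seed = as.integer(seed))
}

#' Displacement sample in the doubled frame
#'
#' Translates landmark `j` to the centre of a frame twice the source size and
#' returns where landmark `i` lands: `l_i + T`, with
#' `T = (W, H) - l_j` for a source frame (H, W). The output minus the doubled
#' centre is exactly the displacement `l_i - l_j`.
#'
#' @param li,lj numeric (u, v) positions of landmarks i and j.
#' @param frame source frame (H, W).
#' @return numeric (u, v) in the doubled frame.
#' @export
displacementSample <- function(li, lj, frame) {
  ctr <- c(frame[2], frame[1]) # (u, v) centre of the (2H, 2W) frame
  li + (ctr - lj)
}

# 2-D Gaussian density on grids (vectorized over the grid).
dmvnorm2Grid <- function(u, v, mu, Sigma) {
  det <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2
  inv <- matrix(c(Sigma[2, 2], -Sigma[1, 2], -Sigma[1, 2], Sigma[1, 1]), 2, 2) / det
  du <- u - mu[1]; dv <- v - mu[2]
  q <- inv[1, 1] * du^2 + 2 * inv[1, 2] * du * dv + inv[2, 2] * dv^2
  exp(-q / 2) / (2 * pi * sqrt(det))
}

# Rasterize a mixture (weights, means list, covs list) on the doubled grid.
rasterizeMixture <- function(fit, frame, gridStep = 1L) {
  dimsOut <- 2L * frame %/% gridStep
  pos <- function(n) (seq_len(n) - 1) * gridStep
  u <- matrix(rep(pos(dimsOut[2]), each = dimsOut[1]), dimsOut[1], dimsOut[2])
  v <- matrix(rep(pos(dimsOut[1]), dimsOut[2]), dimsOut[1], dimsOut[2])
  g <- matrix(0, dimsOut[1], dimsOut[2])
  for (k in seq_along(fit$weights))
    g <- g + fit$weights[k] * dmvnorm2Grid(u, v, fit$means[[k]], fit$covs[[k]])
  g
}

# Fit GMMs with 1..G components (full covariance, EM with deterministic
# model-based hierarchical initialization) and select the component count
# minimizing the mean of AIC and BIC; ties go to fewer components.
selectGmm <- function(samples, maxComponents, ridge, seed) {
  n <- nrow(samples)
  best <- NULL
  hcInit <- tryCatch(suppressWarnings(mclust::hcVVV(samples)),
                     error = function(e) NULL)
  withSeed(seed, {
    for (g in seq_len(maxComponents)) {
      fit <- tryCatch(suppressWarnings({
        z0 <- if (g == 1) matrix(1, n, 1)
              else mclust::unmap(mclust::hclass(hcInit, g))
        ms <- mclust::mstepVVV(samples, z0)
        em <- mclust::emVVV(samples, parameters = ms$parameters)
        if (is.null(em$loglik) || !is.finite(em$loglik)) NULL else em
      }), error = function(e) NULL)
      if (is.null(fit)) next
      df <- mclust::nMclustParams("VVV", d = 2, G = g)
      aic <- -2 * fit$loglik + 2 * df
      bic <- -2 * fit$loglik + df * log(n)
      score <- (aic + bic) / 2
      if (is.null(best) || score < best$score - 1e-9) {
        pro <- fit$parameters$pro
        mu <- fit$parameters$mean
        if (is.null(dim(mu))) mu <- matrix(mu, ncol = g)
        sig <- fit$parameters$variance$sigma
        best <- list(score = score, G = g, weights = pro,
                     means = lapply(seq_len(g), function(k) mu[, k]),
                     covs = lapply(seq_len(g), function(k)
                       sig[, , k] + diag(ridge, 2)))
      }
    }
  })
  if (is.null(best)) {
    # degenerate data (e.g., identical samples): single ridge-floored Gaussian
    mu <- colMeans(samples)
    S <- stats::cov(samples)
    if (any(!is.finite(S))) S <- matrix(0, 2, 2)
    best <- list(score = Inf, G = 1L, weights = 1,
                 means = list(mu), covs = list(S + diag(max(ridge, 1e-3), 2)))
  }
  best
}

#' Fit a conditional displacement prior from samples
#'
#' Fits Gaussian mixtures with 1 to `maxComponents` full-covariance
#' components to the displacement samples (positions of landmark i in the
#' doubled frame centred on landmark j), selects the component count with the
#' lowest mean of AIC and BIC, and rasterizes the selected mixture density at
#' pixel centres of the doubled grid. The grid is left unnormalized: the
#' refinement treats it as an energy, so only its shape matters.
#'
#' @param samples n x 2 matrix of doubled-frame (u, v) samples
#'   (see [displacementSample()]).
#' @param frame source frame (H, W).
#' @param cfg a [gmmFitConfig()].
#' @param pair ordered integer pair (i, j) recorded on the result.
#' @param gridStep pixel spacing for the rasterized grid (1 = full
#'   resolution; the refinement layer typically uses its working resolution).
#' @return a [ConditionalPrior-class].
#' @export
fitConditional <- function(samples, frame, cfg = gmmFitConfig(),
                           pair = c(0L, 0L), gridStep = 1L) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) stop("insufficient data: need at least 2 displacement samples")
  maxG <- max(1L, min(cfg$maxComponents, nrow(samples) %/% 2L))
  fit <- selectGmm(samples, maxG, cfg$ridge, cfg$seed)
  grid <- rasterizeMixture(fit, as.integer(frame), as.integer(gridStep))
  new("ConditionalPrior", pair = as.integer(pair), grid = grid,
      nComponents = as.integer(fit$G), frame = as.integer(frame),
      gridStep = as.integer(gridStep))
}

#' Build the full conditional-prior bank for a topology
#'
#' For every ordered pair (i, j) with j in the extended neighborhood of i,
#' collects `samplesPerImage` spatially augmented coordinate draws per
#' training image (spatial transforms only: translation/rotation/elastic;
#' intensity and occlusion perturbations do not move landmarks), converts
#' them to doubled-frame displacement samples and fits the mixture prior.
#'
#' @param landmarks list of [LandmarkSet-class] (training split).
#' @param topology a [Topology-class].
#' @param frame source frame (H, W).
#' @param augCfg an [augmentConfig()] for the spatial draws (or `NULL` to use
#'   the raw annotations once per image).
#' @param cfg a [gmmFitConfig()].
#' @param gridStep pixel spacing of the rasterized grids.
#' @return a [PriorBank-class] covering exactly the topology's message pairs.
#' @export
buildPriorBank <- function(landmarks, topology, frame, augCfg = augmentConfig(),
                           cfg = gmmFitConfig(), gridStep = 1L) {
  L <- topology@nLandmarks
  draws <- list()
  withSeed(cfg$seed, {
    reps <- if (is.null(augCfg)) 1L else cfg$samplesPerImage
    for (img in landmarks) {
      for (s in seq_len(reps)) {
        lm <- if (is.null(augCfg)) img
              else spatialTransform(NULL, img, augCfg)$landmarks
        draws[[length(draws) + 1]] <- lm
      }
    }
  })
  priors <- list()
  for (i in seq_len(L)) {
    for (j in extendedNeighborhood(topology, i)) {
      pts <- do.call(rbind, lapply(draws, function(lm) {
        vis <- landmarkVisible(lm)
        if (!vis[i] || !vis[j]) return(NULL)
        co <- landmarkCoords(lm)
        displacementSample(co[i, ], co[j, ], frame)
      }))
      if (is.null(pts) || nrow(pts) < 2)
        stop(sprintf("cannot build prior p(%d|%d): landmark pair never visible together", i, j))
      priors[[paste0(i, "|", j)]] <-
        fitConditional(pts, frame, cfg, pair = c(i, j), gridStep = gridStep)
    }
  }
  new("PriorBank", priors = priors, frame = as.integer(frame), topology = topology)
}

#' Persist / restore a prior bank
#'
#' The bank is stored as an R data stream (RDS) next to a JSON metadata twin
#' (frame, pair keys, component counts, grid step).
#'
#' @param bank a [PriorBank-class].
#' @param path RDS path; metadata goes to `<path>.json`.
#' @export
savePriorBank <- function(bank, path) {
  saveRDS(bank, path)
  meta <- list(frame = bank@frame,
               pairs = names(bank@priors),
               n_components = vapply(bank@priors, function(p) p@nComponents, integer(1)),
               grid_step = if (length(bank@priors)) bank@priors[[1]]@gridStep else NA)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname savePriorBank
#' @export
readPriorBank <- function(path) readRDS(path)
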