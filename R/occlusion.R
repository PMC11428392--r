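# Occlusion test protocol: finger sampling, circle-chain occlusion rendering,
# multi-run averaged evaluation.

#' Occlusion test configuration
#'
#' @param fingerSelectProb probability of selecting each finger (default 1/5).
#' @param circleRadiusPx circle radius for a 256-frame (default 10); scaled
#'   proportionally for other frame sizes.
#' @param noiseSd Gaussian noise sd added to the zeroed circles (default 0.02).
#' @param runsPerFold number of randomly sampled test runs averaged per fold
#'   (default 30).
#' @param distalSuffix if TRUE (default) the occluded joint pairs of a
#'   selected finger form a contiguous distal suffix (an amputation-like
#'   pattern from the fingertip inward); if FALSE one joint pair is sampled
#'   uniformly instead.
#' @param seed RNG seed.
#' @return a config list.
#' @export
occlusionTestConfig <- function(fingerSelectProb = 0.2, circleRadiusPx = 10,
                                noiseSd = 0.02, runsPerFold = 30L,
                                distalSuffix = TRUE, seed = 1L) {
  stopifnot(fingerSelectProb > 0 || fingerSelectProb == 0,
            fingerSelectProb <= 1, circleRadiusPx > 0)
  list(fingerSelectProb = fingerSelectProb, circleRadiusPx = circleRadiusPx,
       noiseSd = noiseSd, runsPerFold = as.integer(runsPerFold),
       distalSuffix = distalSuffix, seed = as.integer(seed))
}

#' Sample an occlusion plan for one image
#'
#' Each finger is selected independently with `fingerSelectProb`; for every
#' selected finger a contiguous distal suffix of neighboring joint pairs is
#' chosen uniformly, including the empty suffix, so a selected finger may
#' still end up unoccluded.
#'
#' @param grouping finger chains, see [fingerGrouping()].
#' @param cfg an [occlusionTestConfig()].
#' @param seed optional integer seed.
#' @return list of integer pairs (l_i, l_{i+1}) to occlude (possibly empty).
#' @export
sampleOcclusionPlan <- function(grouping = fingerGrouping(),
                                cfg = occlusionTestConfig(), seed = NULL) {
  withSeed(seed, {
    plan <- list()
    for (chain in grouping) {
      if (stats::runif(1) >= cfg$fingerSelectProb) next
      npairs <- length(chain) - 1L
      if (cfg$distalSuffix) {
        k <- sample.int(npairs + 1L, 1L) - 1L  # 0..npairs pairs, distal first
        if (k > 0)
          for (m in seq_len(k)) {
            idx <- length(chain) - m
            plan[[length(plan) + 1]] <- c(chain[idx], chain[idx + 1L])
          }
      } else {
        idx <- sample.int(npairs, 1L)
        plan[[length(plan) + 1]] <- c(chain[idx], chain[idx + 1L])
      }
    }
    plan
  })
}

#' Occlude the segment between two landmarks with a circle chain
#'
#' Computes `v = l_i - l_{i+1}`, the circle count `c = floor(||v|| / r)` and
#' the step `t = v / c`, then fills circles of radius `r` centred at
#' `l_{i+1} + k t` for `k = 0..c` with intensity zero plus Gaussian noise, so
#' both endpoint joints are covered and the circles overlap into a connected
#' strip. Endpoints closer than `r` get a single circle at their midpoint.
#' Circles are clipped at the frame border; pixels farther than `r` from
#' every centre are untouched.
#'
#' @param image numeric H x W matrix.
#' @param li,lip1 numeric (u, v) endpoints.
#' @param r circle radius in px.
#' @param noiseSd Gaussian noise sd (default 0.02).
#' @param seed optional integer seed.
#' @return list(image, centers = (c+1) x 2 matrix).
#' @export
occludeSegment <- function(image, li, lip1, r, noiseSd = 0.02, seed = NULL) {
  if (r <= 0) stop("radius must be positive")
  if (all(li == lip1)) stop("endpoints must be distinct")
  withSeed(seed, {
    v <- li - lip1
    cc <- floor(sqrt(sum(v^2)) / r)
    centers <- if (cc == 0) rbind((li + lip1) / 2)
    else {
      tt <- v / cc
      t(vapply(0:cc, function(k) lip1 + k * tt, numeric(2)))
    }
    H <- nrow(image); W <- ncol(image)
    g <- coordGrids(H, W)
    inside <- matrix(FALSE, H, W)
    for (k in seq_len(nrow(centers)))
      inside <- inside | ((g$u - centers[k, 1])^2 + (g$v - centers[k, 2])^2 <= r^2)
    n <- sum(inside)
    if (n > 0) image[inside] <- 0 + stats::rnorm(n, 0, noiseSd)
    list(image = image, centers = centers)
  })
}

#' Apply a sampled occlusion plan to one image
#'
#' @param image numeric H x W matrix.
#' @param landmarks the image's [LandmarkSet-class] (annotations are never
#'   modified; they only position the circles).
#' @param plan from [sampleOcclusionPlan()].
#' @param cfg an [occlusionTestConfig()]; the circle radius is scaled by
#'   `H / 256` for non-256 frames.
#' @param seed optional integer seed.
#' @return the occluded image matrix.
#' @export
applyOcclusionPlan <- function(image, landmarks, plan,
                               cfg = occlusionTestConfig(), seed = NULL) {
  if (!length(plan)) return(image)
  r <- cfg$circleRadiusPx * nrow(image) / 256
  co <- landmarkCoords(landmarks)
  withSeed(seed, {
    for (pair in plan) {
      image <- occludeSegment(image, co[pair[1], ], co[pair[2], ], r,
                              noiseSd = cfg$noiseSd)$image
    }
    image
  })
}

#' Run the multi-run averaged occlusion evaluation
#'
#' For each of `runsPerFold` seeded runs: sample an occlusion plan per test
#' image, occlude, predict with the supplied predictor and compute point
#' errors over all landmarks (occluded ones included — targets are
#' unchanged). Outlier counts are averaged across runs and percentages
#' computed from the averaged counts; error statistics are averaged across
#' runs.
#'
#' @param predictor function(image) returning an L x 2 coordinate matrix.
#' @param images list of test image matrices.
#' @param landmarks list of matching [LandmarkSet-class] annotations.
#' @param cfg an [occlusionTestConfig()].
#' @param grouping finger chains, see [fingerGrouping()].
#' @param radiiMm outlier radii (default 2, 4, 10).
#' @param scales per-image mm-per-pixel constants (default: computed from
#'   the wrist pair of each annotation).
#' @return a [MetricsSummary-class] of run-averaged statistics, with the
#'   per-run summaries attached as attribute `"runs"`.
#' @export
runOcclusionEval <- function(predictor, images, landmarks,
                             cfg = occlusionTestConfig(),
                             grouping = fingerGrouping(),
                             radiiMm = c(2, 4, 10), scales = NULL) {
  if (is.null(scales))
    scales <- vapply(landmarks, normalizationConstant, numeric(1))
  runs <- vector("list", cfg$runsPerFold)
  for (run in seq_len(cfg$runsPerFold)) {
    errs <- c()
    for (m in seq_along(images)) {
      sd <- deriveSeed(cfg$seed, run, m)
      plan <- sampleOcclusionPlan(grouping, cfg, seed = sd)
      img <- applyOcclusionPlan(images[[m]], landmarks[[m]], plan, cfg,
                                seed = deriveSeed(sd, 1))
      pred <- predictor(img)
      vis <- landmarkVisible(landmarks[[m]])
      co <- landmarkCoords(landmarks[[m]])
      errs <- c(errs, pointError(pred[vis, , drop = FALSE],
                                 co[vis, , drop = FALSE], scales[[m]]))
    }
    runs[[run]] <- summarizeErrors(errs, radiiMm)
  }
  counts <- rowMeans(vapply(runs, function(s) s@outlierCounts,
                            numeric(length(radiiMm))))
  n <- runs[[1]]@nPredictions
  out <- new("MetricsSummary",
             medianMm = mean(vapply(runs, function(s) s@medianMm, numeric(1))),
             meanMm = mean(vapply(runs, function(s) s@meanMm, numeric(1))),
             sdMm = mean(vapply(runs, function(s) s@sdMm, numeric(1))),
             outlierCounts = counts,
             outlierPct = 100 * counts / n,
             nPredictions = as.integer(n))
  attr(out, "runs") <- runs
  out
}
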