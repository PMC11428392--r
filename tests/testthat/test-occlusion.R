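test_that("the plan sampler respects the per-finger selection probability", {
  cfg0 <- occlusionTestConfig(fingerSelectProb = 0)
  expect_equal(length(sampleOcclusionPlan(cfg = cfg0, seed = 1)), 0L)
  cfg <- occlusionTestConfig(fingerSelectProb = 0.2)
  set.seed(77)
  hits <- 0L; draws <- 10000L
  for (k in seq_len(draws)) {
    # count selection of the first finger: a plan with any thumb pair
    plan <- sampleOcclusionPlan(fingerGrouping()[1], cfg)
    # selection may still yield the empty suffix; count via RNG replication
    hits <- hits + length(plan)
  }
  # each selection contributes 0..3 pairs uniformly (mean 1.5), so the
  # expected pairs per draw is 0.2 * 1.5 = 0.3
  expect_equal(hits / draws, 0.3, tolerance = 0.015)
  # direct frequency of the selection event itself
  set.seed(78)
  sel <- mean(replicate(10000, length(sampleOcclusionPlan(
    fingerGrouping()["thumb"], occlusionTestConfig(fingerSelectProb = 0.2,
                                                   distalSuffix = FALSE))) > 0))
  # a selected thumb contributes a pair with probability 1 here
  expect_lt(abs(sel - 0.2), 0.012)
})

test_that("plans only ever name occludable finger joints", {
  cfg <- occlusionTestConfig(fingerSelectProb = 1)
  occludable <- unlist(fingerGrouping())
  set.seed(3)
  for (k in 1:50) {
    plan <- sampleOcclusionPlan(cfg = cfg)
    for (pair in plan) expect_true(all(pair %in% occludable))
  }
})

test_that("the circle chain follows the worked geometry", {
  img <- matrix(0.5, 64, 64)
  r <- occludeSegment(img, li = c(30, 0), lip1 = c(0, 0), r = 10,
                      noiseSd = 0, seed = 1)
  # c = floor(30 / 10) = 3, step (10, 0), centres at 0, 10, 20, 30 on the axis
  expect_equal(nrow(r$centers), 4)
  expect_equal(r$centers[, 1], c(0, 10, 20, 30))
  expect_equal(r$centers[, 2], rep(0, 4))
  # both endpoints are covered
  expect_equal(r$image[1, 1], 0)
  expect_equal(r$image[1, 31], 0)
  # pixels farther than the radius from every centre are unchanged
  g <- coordGrids(64, 64)
  dmin <- Reduce(pmin, lapply(1:4, function(k)
    sqrt((g$u - r$centers[k, 1])^2 + (g$v - r$centers[k, 2])^2)))
  expect_true(all(r$image[dmin > 10] == 0.5))
  expect_true(all(r$image[dmin <= 10] == 0))
})

test_that("close endpoints get a single midpoint circle", {
  img <- matrix(1, 32, 32)
  r <- occludeSegment(img, c(10, 10), c(14, 10), r = 10, noiseSd = 0)
  expect_equal(nrow(r$centers), 1)
  expect_equal(r$centers[1, ], c(12, 10))
  expect_error(occludeSegment(img, c(5, 5), c(5, 5), r = 3), "distinct")
  expect_error(occludeSegment(img, c(1, 1), c(9, 9), r = 0), "positive")
})

test_that("occlusion noise only touches the circle union and not annotations", {
  set.seed(5)
  img <- matrix(runif(64 * 64), 64, 64)
  co <- rbind(c(10, 10), c(40, 40))
  lm <- LandmarkSet(co)
  plan <- list(c(1L, 2L))
  out <- applyOcclusionPlan(img, lm, plan, occlusionTestConfig(), seed = 2)
  expect_equal(dim(out), dim(img))
  expect_equal(landmarkCoords(lm), co, ignore_attr = TRUE)  # annotations untouched
  changed <- which(out != img, arr.ind = TRUE)
  v <- co[1, ] - co[2, ]
  cc <- floor(sqrt(sum(v^2)) / (10 * 64 / 256))
  centres <- t(vapply(0:cc, function(k) co[2, ] + k * v / cc, numeric(2)))
  rad <- 10 * 64 / 256
  dmin <- apply(changed, 1, function(px)
    min(sqrt((px[2] - 1 - centres[, 1])^2 + (px[1] - 1 - centres[, 2])^2)))
  expect_true(all(dmin <= rad + 1e-9))
})

test_that("a zero-probability protocol reproduces the standard evaluation", {
  set.seed(6)
  imgs <- lapply(1:3, function(k) matrix(runif(64 * 64), 64, 64))
  co <- rbind(c(10, 10), c(10, 60), c(30, 30))
  co <- rbind(co, matrix(runif(2 * 34, 5, 58), 34, 2))  # 37 landmarks
  lms <- lapply(1:3, function(k) LandmarkSet(co, imageId = paste0("i", k)))
  predictor <- function(img) co + 1   # constant 1-px offset in u and v
  scales <- rep(1, 3)
  occ <- runOcclusionEval(predictor, imgs, lms,
                          occlusionTestConfig(fingerSelectProb = 1e-12,
                                              runsPerFold = 2L),
                          scales = scales)
  std <- evaluateStandard(predictor, imgs, lms, scales = scales)
  expect_equal(occ@meanMm, std@meanMm, tolerance = 1e-9)
  expect_equal(unname(occ@outlierCounts), unname(std@outlierCounts))
})

test_that("seeded occlusion runs are bit-reproducible", {
  set.seed(6)
  imgs <- lapply(1:2, function(k) matrix(runif(64 * 64), 64, 64))
  co <- handTemplate(c(64L, 64L))
  lms <- lapply(1:2, function(k) LandmarkSet(co, imageId = paste0("i", k)))
  predictor <- function(img) co + matrix(c(1, 0), 37, 2, byrow = TRUE)
  cfg <- occlusionTestConfig(fingerSelectProb = 0.5, runsPerFold = 3L,
                             seed = 11L)
  a <- runOcclusionEval(predictor, imgs, lms, cfg, scales = rep(1, 2))
  b <- runOcclusionEval(predictor, imgs, lms, cfg, scales = rep(1, 2))
  expect_identical(a@meanMm, b@meanMm)
  expect_identical(a@outlierCounts, b@outlierCounts)
})
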