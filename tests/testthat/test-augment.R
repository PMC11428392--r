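test_that("zero-range transforms are the identity", {
  cfg <- augmentConfig(resizeTo = c(32L, 32L), translatePx = c(0, 0),
                       rotateRad = c(0, 0), elasticAmpPx = 0)
  set.seed(1)
  img <- matrix(runif(32 * 32), 32, 32)
  lm <- LandmarkSet(rbind(c(5, 7), c(20, 25)))
  st <- spatialTransform(img, lm, cfg, seed = 4)
  expect_equal(st$image, img, tolerance = 1e-12)
  expect_equal(landmarkCoords(st$landmarks), landmarkCoords(lm))
  expect_true(all(landmarkVisible(st$landmarks)))
})

test_that("a pure translation moves every landmark rigidly", {
  cfg <- augmentConfig(resizeTo = c(32L, 32L), translatePx = c(5, 5),
                       rotateRad = c(0, 0), elasticAmpPx = 0)
  lm <- LandmarkSet(rbind(c(5, 7), c(20, 25), c(10, 3)))
  st <- spatialTransform(NULL, lm, cfg, seed = 1)
  expect_equal(landmarkCoords(st$landmarks)[, 1],
               landmarkCoords(lm)[, 1] + 5)
  expect_equal(landmarkCoords(st$landmarks)[, 2],
               landmarkCoords(lm)[, 2] + 5)
})

test_that("rotation about the centre fixes the central landmark", {
  cfg <- augmentConfig(resizeTo = c(33L, 33L), translatePx = c(0, 0),
                       rotateRad = c(0.2, 0.2), elasticAmpPx = 0)
  lm <- LandmarkSet(rbind(c(16, 16), c(26, 16)))
  st <- spatialTransform(NULL, lm, cfg, seed = 2)
  expect_equal(landmarkCoords(st$landmarks)[1, ], c(16, 16),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_gt(max(abs(landmarkCoords(st$landmarks)[2, ] - c(26, 16))), 0.5)
})

test_that("a marker painted at a landmark follows it through the warp", {
  set.seed(9)
  cfg <- augmentConfig(resizeTo = c(64L, 64L), translatePx = c(-6, 6),
                       elasticAmpPx = 6)
  for (seed in c(3, 14, 27)) {
    img <- matrix(0, 64, 64)
    lm0 <- c(24, 37)
    img[lm0[2] + 1, lm0[1] + 1] <- 1
    st <- spatialTransform(img, LandmarkSet(rbind(lm0)), cfg, seed = seed)
    if (!landmarkVisible(st$landmarks)[1]) next
    pk <- which(st$image == max(st$image), arr.ind = TRUE)[1, ]
    co <- landmarkCoords(st$landmarks)[1, ]
    expect_lt(sqrt((pk[2] - 1 - co[1])^2 + (pk[1] - 1 - co[2])^2), 1)
  }
})

test_that("intensity augmentation normalizes, shifts, then rescales", {
  cfg0 <- augmentConfig(resizeTo = c(8L, 8L), intensityShift = c(0, 0),
                        intensityScale = c(0, 0))
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  out <- intensityTransform(img, cfg0, seed = 1)
  expect_equal(out, 2 * img - 1, tolerance = 1e-12)   # identity after [-1,1]
  # fixed scale: new = old * (1 + v)
  cfgV <- augmentConfig(resizeTo = c(8L, 8L), intensityShift = c(0, 0),
                        intensityScale = c(0.1, 0.1))
  outV <- intensityTransform(img, cfgV, seed = 1)
  expect_equal(outV, (2 * img - 1) * 1.1, tolerance = 1e-12)
  # fixed shift added to every pixel before scaling
  cfgS <- augmentConfig(resizeTo = c(8L, 8L), intensityShift = c(0.15, 0.15),
                        intensityScale = c(0, 0))
  outS <- intensityTransform(img, cfgS, seed = 1)
  expect_equal(outS, (2 * img - 1) + 0.15, tolerance = 1e-12)
  expect_equal(min(outS), -0.85, tolerance = 1e-12)
  # constant image maps to zeros, no division blow-up
  expect_true(all(abs(intensityTransform(matrix(5, 8, 8), cfg0, seed = 1))
                  <= 0.31))
})

test_that("occlusion boxes hit the same location in every batch image", {
  set.seed(2)
  batch <- array(runif(64 * 64 * 4), c(64, 64, 4))
  cfg <- augmentConfig(resizeTo = c(64L, 64L))
  r <- occlusionBoxes(batch, cfg, seed = 8)
  expect_equal(dim(r$batch), dim(batch))
  box <- r$box
  area <- box["w"] * box["h"]
  expect_gte(area / (64 * 64), 0.008)
  expect_lte(area / (64 * 64), 0.16)
  changed <- which(r$batch != batch, arr.ind = TRUE)
  # all modified pixels lie inside the reported box, in every image
  expect_true(all(changed[, 1] >= box["v0"] + 1 &
                  changed[, 1] <= box["v0"] + box["h"]))
  expect_true(all(changed[, 2] >= box["u0"] + 1 &
                  changed[, 2] <= box["u0"] + box["w"]))
  expect_setequal(unique(changed[, 3]), 1:4)
  # disabled: untouched
  off <- augmentConfig(resizeTo = c(64L, 64L), occlusionEnabled = FALSE)
  expect_identical(occlusionBoxes(batch, off, seed = 8)$batch, batch)
})
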