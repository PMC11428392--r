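test_that("zero variation reproduces the template exactly", {
  cfg <- syntheticConfig(nImages = 1, frame = c(64L, 64L), rotation = 0,
                         scaleRange = c(1, 1), translatePx = 0, jitterSd = 0,
                         noiseSd = 0)
  s <- sampleHand(cfg, seed = 1)
  expect_equal(landmarkCoords(s$landmarks), handTemplate(c(64L, 64L)),
               tolerance = 1e-9)
  expect_true(all(landmarkVisible(s$landmarks)))
  # joints render as local intensity maxima
  co <- landmarkCoords(s$landmarks)
  for (i in c(2, 21, 29)) {
    win <- s$image[max(1, round(co[i, 2]) - 1):(round(co[i, 2]) + 3),
                   max(1, round(co[i, 1]) - 1):(round(co[i, 1]) + 3)]
    expect_gt(max(win), 0.9)
  }
})

test_that("different seeds vary the pose but preserve rough bone lengths", {
  cfg <- syntheticConfig(nImages = 1, frame = c(128L, 128L))
  a <- sampleHand(cfg, seed = 1); b <- sampleHand(cfg, seed = 2)
  expect_gt(max(abs(landmarkCoords(a$landmarks) - landmarkCoords(b$landmarks))), 0.5)
  dA <- dist(landmarkCoords(a$landmarks)[c(2, 6), ])
  dB <- dist(landmarkCoords(b$landmarks)[c(2, 6), ])
  # wrist width varies only within the affine scale range (with jitter slack)
  expect_lt(abs(log(dA / dB)), log(1.1 / 0.9) + 0.2)
})

test_that("datasets write the standard layout deterministically", {
  dir1 <- file.path(tempdir(), "synthA"); dir2 <- file.path(tempdir(), "synthB")
  unlink(c(dir1, dir2), recursive = TRUE)
  cfg <- syntheticConfig(nImages = 9, frame = c(64L, 64L), seed = 5)
  makeHandDataset(cfg, dir1)
  makeHandDataset(cfg, dir2)
  expect_equal(length(list.files(file.path(dir1, "images"))), 9)
  expect_equal(length(list.files(file.path(dir1, "annotations"))), 9)
  expect_equal(length(list.files(file.path(dir1, "splits"))), 6)
  # three-fold split: 6 train / 3 test per fold, partitioning the ids
  tr <- readLines(file.path(dir1, "splits", "fold1_train.txt"))
  te <- readLines(file.path(dir1, "splits", "fold1_test.txt"))
  expect_equal(length(tr), 6); expect_equal(length(te), 3)
  expect_equal(length(intersect(tr, te)), 0)
  # byte-identical regeneration
  f <- "annotations/synth0001.csv"
  expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  m <- datasetManifest(dir1)
  expect_equal(length(m$ids), 9)
})

test_that("generated landmarks support learnable wrist priors", {
  cfg <- syntheticConfig(nImages = 24, frame = c(64L, 64L), seed = 7)
  ds <- sampleHandDataset(cfg)
  pts <- t(vapply(ds$landmarks, function(lm) {
    co <- landmarkCoords(lm)
    displacementSample(co[2, ], co[6, ], c(64L, 64L))
  }, numeric(2)))
  pr <- fitConditional(pts, c(64L, 64L), gmmFitConfig(seed = 1))
  expect_equal(pr@nComponents, 1L)   # unimodal displacement cloud
})
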