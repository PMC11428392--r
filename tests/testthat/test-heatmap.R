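test_that("target blobs peak at the landmark with the configured scaling", {
  h <- renderTarget(c(40, 60), c(128, 128))
  expect_equal(h[61, 41], 1000)
  expect_equal(decodeArgmax(h), c(u = 40, v = 60))
  # closed form on the gaussian profile at distance 3 with sigma 3
  expect_equal(h[61 + 3, 41], 1000 * exp(-0.5), tolerance = 1e-12)
  lap <- renderTarget(c(40, 60), c(128, 128), blobConfig(family = "laplacian"))
  expect_equal(lap[61, 41], 1000)
  expect_equal(lap[61, 41 + 6], 1000 * exp(-2), tolerance = 1e-12)
  far <- renderTarget(c(5000, 5000), c(32, 32))
  expect_true(all(far == 0))
  expect_error(blobConfig(sigma = 0), "sigma")
  expect_error(blobConfig(gamma = -1), "gamma")
})

test_that("argmax decoding breaks ties in row-major scan order", {
  h <- matrix(0, 4, 4)
  h[1, 2] <- 1; h[2, 1] <- 1   # (u=1,v=0) comes first scanning rows
  expect_equal(decodeArgmax(h), c(u = 1, v = 0))
  oneHot <- matrix(0, 5, 7); oneHot[3, 6] <- 2
  expect_equal(decodeArgmax(oneHot), c(u = 5, v = 2))
})

test_that("soft-argmax matches its exact expectations", {
  oneHot <- matrix(0, 9, 9); oneHot[4, 6] <- 3.3
  expect_equal(softArgmax(oneHot), c(u = 5, v = 3))
  unif <- matrix(1, 11, 15)
  expect_equal(softArgmax(unif), c(u = 7, v = 5))   # (W-1)/2, (H-1)/2
  two <- matrix(0, 12, 12); two[1, 1] <- 1; two[1, 11] <- 1
  expect_equal(softArgmax(two), c(u = 5, v = 0))
  expect_error(softArgmax(matrix(0, 4, 4)), "degenerate")
})

test_that("soft-argmax of an in-frame blob agrees with argmax", {
  for (lm in list(c(20, 40), c(33.0, 17.0), c(50, 22))) {
    h <- renderTarget(lm, c(64, 64))
    expect_lt(max(abs(softArgmax(h) - decodeArgmax(h))), 1e-3)
  }
})

test_that("sharpening drives soft-argmax toward argmax", {
  set.seed(7)
  h <- renderTarget(c(17, 42), c(64, 64), blobConfig(sigma = 2, gamma = 1)) +
       0.05 * matrix(runif(64 * 64), 64, 64)
  am <- decodeArgmax(h)
  gap <- function(k) max(abs(softArgmax((h / max(h))^k) - am))
  expect_gt(gap(1), gap(30))
  expect_lt(gap(300), 1e-2)
})

test_that("render then decode recovers in-frame landmarks", {
  set.seed(5)
  for (k in 1:10) {
    lm <- round(runif(2, 5, 58))
    h <- renderTarget(lm, c(64, 64))
    expect_equal(unname(decodeArgmax(h)), lm)
  }
})

test_that("heatmap stacks serialize through float TIFF", {
  skip_if_not_installed("tiff")
  set.seed(2)
  st <- HeatmapStack(array(runif(16 * 16 * 3), c(16, 16, 3)))
  path <- tempfile(fileext = ".tif")
  writeHeatmapStack(st, path)
  back <- readHeatmapStack(path)
  expect_equal(back@grids, st@grids, tolerance = 1e-6)
  expect_equal(heatmapFrame(back), c(16L, 16L))
})
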