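test_that("the SCN output factorizes exactly into local times filter", {
  set.seed(2)
  scn <- scnInit(scnConfig(maps = 4L, downFactor = 2L, kernel = 3L),
                 nLandmarks = 3L, seed = 2)
  loc <- array(abs(rnorm(16 * 16 * 3 * 2)), c(16, 16, 3, 2))
  sf <- scnForward(scn, loc)
  expect_equal(dim(sf$out), dim(loc))
  expect_equal(sf$out, loc * sf$filter, tolerance = 1e-12)
  nz <- loc != 0
  expect_equal((sf$out / loc)[nz], sf$filter[nz], tolerance = 1e-9)
  # a zero filter annihilates the corresponding local values
  loc2 <- loc; loc2[, , 1, ] <- 0
  sf2 <- scnForward(scn, loc2)
  expect_true(all(sf2$out[, , 1, ] == 0))
})

test_that("SCN training gradients match finite differences", {
  set.seed(4)
  scn <- scnInit(scnConfig(maps = 3L, downFactor = 2L, kernel = 3L),
                 nLandmarks = 2L, seed = 4)
  loc <- array(abs(rnorm(8 * 8 * 2 * 2)), c(8, 8, 2, 2))
  tgt <- array(abs(rnorm(8 * 8 * 2 * 2)), c(8, 8, 2, 2))
  sf <- scnForward(scn, loc, training = TRUE)
  hl <- heatmapLoss(sf$out, tgt)
  sb <- scnBackward(scn, sf$cache, hl$grad)
  lossOf <- function(m, l) heatmapLoss(scnForward(m, l, training = TRUE)$out,
                                       tgt)$loss
  eps <- 1e-5
  m2 <- scn; m2$params$sc1$w[3, 2] <- m2$params$sc1$w[3, 2] + eps
  m3 <- scn; m3$params$sc1$w[3, 2] <- m3$params$sc1$w[3, 2] - eps
  expect_equal(sb$grads$sc1$w[3, 2],
               (lossOf(m2, loc) - lossOf(m3, loc)) / (2 * eps),
               tolerance = 1e-4)
  l2 <- loc; l2[4, 7, 2, 1] <- l2[4, 7, 2, 1] + eps
  l3 <- loc; l3[4, 7, 2, 1] <- l3[4, 7, 2, 1] - eps
  expect_equal(sb$glocal[4, 7, 2, 1],
               (lossOf(scn, l2) - lossOf(scn, l3)) / (2 * eps),
               tolerance = 1e-4)
})
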