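test_that("displacement samples centre the conditioning landmark", {
  frame <- c(256L, 256L)
  expect_equal(displacementSample(c(50, 80), c(50, 80), frame), c(256, 256))
  expect_equal(displacementSample(c(110, 100), c(100, 100), frame), c(266, 256))
  set.seed(1)
  for (k in 1:10) {
    li <- runif(2, 0, 255); lj <- runif(2, 0, 255)
    out <- displacementSample(li, lj, frame)
    expect_equal(out - c(256, 256), li - lj)
  }
})

test_that("mixture fitting recovers a single displacement cluster", {
  set.seed(42)
  frame <- c(64L, 64L)
  mu <- c(70, 58)
  samples <- cbind(rnorm(500, mu[1], 5), rnorm(500, mu[2], 5))
  pr <- fitConditional(samples, frame, gmmFitConfig(seed = 1), pair = c(1L, 2L))
  expect_equal(pr@nComponents, 1L)
  am <- which(pr@grid == max(pr@grid), arr.ind = TRUE)[1, ]
  expect_lt(sqrt((am[2] - 1 - mu[1])^2 + (am[1] - 1 - mu[2])^2), 2)
})

test_that("mixture selection finds two well-separated clusters", {
  set.seed(43)
  frame <- c(64L, 64L)
  s1 <- cbind(rnorm(250, 30, 2), rnorm(250, 40, 2))
  s2 <- cbind(rnorm(250, 90, 2), rnorm(250, 95, 2))
  pr <- fitConditional(rbind(s1, s2), frame, gmmFitConfig(seed = 1))
  expect_equal(pr@nComponents, 2L)
})

test_that("degenerate samples survive through the covariance floor", {
  frame <- c(32L, 32L)
  same <- matrix(rep(c(20, 25), each = 50), ncol = 2)
  pr <- fitConditional(same, frame, gmmFitConfig(seed = 1))
  expect_true(all(is.finite(pr@grid)))
  am <- which(pr@grid == max(pr@grid), arr.ind = TRUE)[1, ]
  expect_equal(unname(c(am[2] - 1, am[1] - 1)), c(20, 25))
  expect_error(fitConditional(matrix(c(1, 2), 1, 2), frame), "insufficient")
})

test_that("the bank covers every message pair and mirrors ordered pairs", {
  topo <- chainTopology3()
  frame <- c(32L, 32L)
  set.seed(4)
  lms <- lapply(1:6, function(k)
    LandmarkSet(rbind(c(8, 8), c(16, 16), c(24, 20)) +
                matrix(rnorm(6, 0, 0.8), 3, 2), imageId = paste0("i", k)))
  bank <- buildPriorBank(lms, topo, frame, augCfg = NULL,
                         cfg = gmmFitConfig(maxComponents = 1L, seed = 2L))
  expect_equal(length(bank), nrow(messagePairs(topo)))
  # p(i|j) is the point reflection of p(j|i) about the doubled-frame centre
  g12 <- bankPrior(bank, 1, 2)@grid
  g21 <- bankPrior(bank, 2, 1)@grid
  flip <- g21[nrow(g21):1, ncol(g21):1]
  # mode positions mirror (densities are smooth, compare peak locations)
  a <- which(g12 == max(g12), arr.ind = TRUE)[1, ]
  b <- which(flip == max(flip), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(a - (b - 1))), 2)
  # a pair that is never visible together is a hard error naming the pair
  lms2 <- lapply(lms, function(l)
    LandmarkSet(landmarkCoords(l), c(TRUE, TRUE, FALSE), imageId(l)))
  expect_error(buildPriorBank(lms2, topo, frame, augCfg = NULL,
                              cfg = gmmFitConfig(maxComponents = 1L)),
               "3\\|2|2\\|3")
})

test_that("the wrist displacement prior concentrates at one wrist width", {
  set.seed(6)
  cfg <- syntheticConfig(nImages = 30, frame = c(64L, 64L), seed = 9)
  ds <- sampleHandDataset(cfg)
  pts <- t(vapply(ds$landmarks, function(lm) {
    co <- landmarkCoords(lm)
    displacementSample(co[2, ], co[6, ], c(64L, 64L))
  }, numeric(2)))
  pr <- fitConditional(pts, c(64L, 64L), gmmFitConfig(seed = 3))
  am <- which(pr@grid == max(pr@grid), arr.ind = TRUE)[1, ]
  tmpl <- handTemplate(c(64L, 64L))
  expected <- c(64, 64) + (tmpl[2, ] - tmpl[6, ])
  expect_lt(sqrt(sum((c(am[2], am[1]) - 1 - expected)^2)), 3)
})

test_that("prior banks persist with their metadata twin", {
  topo <- chainTopology3()
  bank <- randomBank(topo, c(16L, 16L), gridStep = 2L)
  f <- tempfile(fileext = ".rds")
  savePriorBank(bank, f)
  back <- readPriorBank(f)
  expect_equal(length(back), length(bank))
  meta <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_setequal(meta$pairs, names(bank@priors))
})
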