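test_that("the softplus rectifier matches its closed form", {
  expect_equal(softplusBeta(0, 5), log(2) / 5)
  expect_equal(softplusBeta(-100, 5), 0, tolerance = 1e-12)
  expect_equal(softplusBeta(50, 5), 50, tolerance = 1e-10)
  expect_gt(softplusBeta(1), softplusBeta(0))
  xs <- seq(-2, 2, by = 0.05)
  expect_true(all(diff(softplusBeta(xs)) > 0))
  expect_true(all(softplusBeta(xs) > 0))
})

test_that("the unary energy is the log-softplus of the heatmap", {
  expect_equal(unaryEnergy(0), log(softplusBeta(1e-6)), tolerance = 1e-12)
  expect_equal(unaryEnergy(0), -1.9760, tolerance = 1e-4)
  set.seed(1)
  h <- matrix(rnorm(100), 10, 10)
  expect_equal(decodeArgmax(unaryEnergy(h)), decodeArgmax(h))
  expect_true(all(is.finite(unaryEnergy(h * 1e6))))
})

test_that("Fourier, Toeplitz and direct message convolutions agree", {
  set.seed(12)
  for (h in c(5, 8)) {
    m <- matrix(rnorm(h * h), h, h)
    K <- matrix(rnorm(4 * h * h), 2 * h, 2 * h)
    ref <- messageConvolve(m, K, "direct")
    expect_equal(messageConvolve(m, K, "fft"), ref, tolerance = 1e-10)
    expect_equal(messageConvolve(m, K, "gemm"), ref, tolerance = 1e-10)
  }
  expect_error(messageConvolve(matrix(0, 4, 4), matrix(0, 4, 4)), "twice")
})

test_that("a delta kernel shifts the map by its displacement", {
  h <- matrix(0, 8, 8); h[3, 5] <- 1            # peak at (u=4, v=2)
  K <- matrix(0, 16, 16); K[8 + 1 + 2, 8 + 1 + 3] <- 1   # displacement (3, 2)
  out <- messageConvolve(h, K, "fft")
  expect_equal(unname(decodeArgmax(out)), c(4 + 3, 2 + 2))
})

test_that("the refinement layer equals the nested-loop energy transcription", {
  set.seed(5)
  topo <- chainTopology3()
  frame <- c(8L, 8L)
  bank <- randomBank(topo, frame, seed = 5)
  heat <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
  ref <- gaffaRefine(array(heat, c(8, 8, 3)), bank, topo,
                     gaffaConfig(downFactor = 1L, kernelStoreFactor = 1L))
  oracle <- refineOracle(array(heat, c(8, 8, 3)), bank, topo)
  expect_lt(max(abs(ref$energies@grids - oracle) /
                pmax(abs(oracle), 1e-9)), 1e-5)
})

test_that("an isolated landmark keeps its unary energy exactly", {
  topo1 <- Topology(2, rbind(c(1, 2)))   # landmark 2 talks to 1 only
  # single-landmark graph: no edges, empty neighborhood
  topoIso <- Topology(1, matrix(integer(0), ncol = 2))
  frame <- c(8L, 8L)
  set.seed(8)
  heat <- array(rnorm(64), c(8, 8, 1, 1))
  bank <- new("PriorBank", priors = list(), frame = frame, topology = topoIso)
  ga <- gaffaInit(bank, topoIso, frame,
                  gaffaConfig(downFactor = 1L, kernelStoreFactor = 1L))
  fw <- gaffaForward(ga, heat, training = FALSE)
  me <- unaryEnergy(heat / sqrt(1 + 1e-8))
  expect_equal(fw$mehat, me, tolerance = 1e-6)
  expect_equal(unname(fw$coords[1, , 1]),
               unname(softArgmax(me[, , 1, 1], normalize = "softmax")),
               tolerance = 1e-8)
})

test_that("an anatomically consistent prior suppresses a spurious peak", {
  # two-landmark chain on 32x32: landmark 1 bimodal (true + spurious peak),
  # landmark 2 sharp; the prior links 1 to 2 at the true displacement
  frame <- c(32L, 32L)
  topo <- Topology(2, rbind(c(1, 2)))
  true1 <- c(10, 12); spur1 <- c(25, 25); lm2 <- c(16, 20)
  h1 <- renderTarget(true1, frame, blobConfig(sigma = 1.5, gamma = 1)) +
        1.2 * renderTarget(spur1, frame, blobConfig(sigma = 1.5, gamma = 1))
  h2 <- renderTarget(lm2, frame, blobConfig(sigma = 1.5, gamma = 1))
  disp <- list("1|2" = true1 - lm2, "2|1" = lm2 - true1)
  bank <- deltaBank(topo, frame, disp, amplitude = 50)
  heat <- array(c(h1, h2), c(32, 32, 2, 1))
  # spurious peak wins before refinement ...
  expect_equal(unname(decodeArgmax(h1)), spur1)
  ref <- gaffaRefine(array(heat, c(32, 32, 2)), bank, topo,
                     gaffaConfig(downFactor = 1L, kernelStoreFactor = 1L))
  # ... but the true mode wins after
  am <- decodeArgmax(heatmapChannel(ref$energies, 1))
  expect_lt(sqrt(sum((am - true1)^2)), 2)
  expect_equal(dim(ref$energies@grids)[1:2], c(32L, 32L))
})

test_that("translating heatmaps with shift-consistent priors shifts the result", {
  frame <- c(16L, 16L)
  topo <- Topology(2, rbind(c(1, 2)))
  mk <- function(c1, c2) {
    h1 <- renderTarget(c1, frame, blobConfig(sigma = 1, gamma = 1))
    h2 <- renderTarget(c2, frame, blobConfig(sigma = 1, gamma = 1))
    array(c(h1, h2), c(16, 16, 2))
  }
  disp <- list("1|2" = c(-2, -3), "2|1" = c(2, 3))
  bank <- deltaBank(topo, frame, disp)
  cfg <- gaffaConfig(downFactor = 1L, kernelStoreFactor = 1L)
  r1 <- gaffaRefine(mk(c(6, 5), c(8, 8)), bank, topo, cfg)
  r2 <- gaffaRefine(mk(c(8, 7), c(10, 10)), bank, topo, cfg)
  a1 <- decodeArgmax(heatmapChannel(r1$energies, 1))
  a2 <- decodeArgmax(heatmapChannel(r2$energies, 1))
  expect_equal(unname(a2 - a1), c(2, 2))
})

test_that("rescaling the prior bank leaves initial argmax decisions unchanged", {
  # scale tolerance holds where the convolved energies dominate the softplus
  # floor of the bias term; rescale within that regime
  set.seed(21)
  topo <- chainTopology3()
  frame <- c(8L, 8L)
  bank <- randomBank(topo, frame, seed = 9)
  heat <- array(1000 * abs(rnorm(8 * 8 * 3)), c(8, 8, 3))
  cfg <- gaffaConfig(downFactor = 1L, kernelStoreFactor = 1L)
  r1 <- gaffaRefine(heat, bank, topo, cfg)
  bank2 <- bank
  for (k in names(bank2@priors)) bank2@priors[[k]]@grid <-
      bank2@priors[[k]]@grid * 3
  r2 <- gaffaRefine(heat, bank2, topo, cfg)
  for (i in 1:3)
    expect_equal(decodeArgmax(heatmapChannel(r1$energies, i)),
                 decodeArgmax(heatmapChannel(r2$energies, i)))
})

test_that("refinement gradients match finite differences", {
  set.seed(5)
  topo <- chainTopology3()
  frame <- c(16L, 16L)
  bank <- randomBank(topo, frame, gridStep = 4L, seed = 3)
  ga <- gaffaInit(bank, topo, frame,
                  gaffaConfig(downFactor = 2L, kernelStoreFactor = 2L))
  heat <- array(rnorm(16 * 16 * 3), c(16, 16, 3, 1))
  tgt <- array(7, c(3, 2, 1))
  lossOf <- function(g, h)
    coordinateLoss(gaffaForward(g, h, training = FALSE)$coords, tgt)$loss
  fw <- gaffaForward(ga, heat, training = FALSE)
  cl <- coordinateLoss(fw$coords, tgt)
  bw <- gaffaBackward(ga, fw$cache, gcoords = cl$grad)
  eps <- 1e-5
  fd <- function(perturb) {
    (lossOf(perturb(ga, eps)$ga %||% ga, perturb(ga, eps)$heat %||% heat) -
     lossOf(perturb(ga, -eps)$ga %||% ga, perturb(ga, -eps)$heat %||% heat)) /
      (2 * eps)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  pk <- function(g, e) { g$params$kernels[["2|1"]][3, 4] <-
      g$params$kernels[["2|1"]][3, 4] + e; list(ga = g, heat = NULL) }
  pb <- function(g, e) { g$params$biases[["3|2"]][4, 4] <-
      g$params$biases[["3|2"]][4, 4] + e; list(ga = g, heat = NULL) }
  ph <- function(g, e) { h2 <- heat; h2[5, 9, 1, 1] <- h2[5, 9, 1, 1] + e
      list(ga = NULL, heat = h2) }
  expect_equal(bw$grads$kernels[["2|1"]][3, 4], fd(pk), tolerance = 1e-4)
  expect_equal(bw$grads$biases[["3|2"]][4, 4], fd(pb), tolerance = 1e-3)
  expect_equal(bw$gheat[5, 9, 1, 1], fd(ph), tolerance = 1e-3)
  expect_true(all(vapply(flattenParams(bw$grads),
                         function(g) all(is.finite(g)), logical(1))))
})

test_that("global messages keep a zeroed landmark near its prior position", {
  # landmark 1's appearance is erased; its only information comes from the
  # message sent by landmark 2 through the displacement prior
  frame <- c(32L, 32L)
  topo <- Topology(2, rbind(c(1, 2)))
  lm2 <- c(16, 18); d <- c(-6, -4)
  h1 <- matrix(0, 32, 32)
  h2 <- renderTarget(lm2, frame, blobConfig(sigma = 1.5, gamma = 1))
  bank <- deltaBank(topo, frame, list("1|2" = d, "2|1" = -d))
  ref <- gaffaRefine(array(c(h1, h2), c(32, 32, 2)), bank, topo,
                     gaffaConfig(downFactor = 1L, kernelStoreFactor = 1L))
  am <- decodeArgmax(heatmapChannel(ref$energies, 1))
  expect_lt(sqrt(sum((am - (lm2 + d))^2)), 2)
})
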