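test_that("the localizer emits one full-resolution heatmap per landmark", {
  cfg <- unetConfig(levels = 4L, width = 4L, outChannels = 37L, dropout = 0)
  m <- unetInit(cfg, seed = 1)
  set.seed(2)
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  fw <- unetForward(m, x)
  expect_equal(dim(fw$out), c(64, 64, 37, 1))
  expect_true(all(is.finite(fw$out)))
  expect_error(unetForward(m, array(0, c(60, 60, 1, 1))), "divisible")
})

test_that("the parameter count matches the closed-form architecture formula", {
  cfg <- unetConfig()   # reference capacity: 4 levels, 128 channels
  m <- unetInit(cfg, seed = 1)
  convP <- function(k, cin, cout) k * k * cin * cout + cout       # w + b
  bnP <- function(cout) 2 * cout                                   # gamma, beta
  w <- cfg$width
  expected <- 0
  for (lv in 1:cfg$levels) {
    cin1 <- if (lv == 1) 1 else w
    expected <- expected + convP(3, cin1, w) + bnP(w) + convP(3, w, w) + bnP(w)
  }
  expected <- expected + cfg$levels * (convP(3, 2 * w, w) + bnP(w) +
                                       convP(3, w, w) + bnP(w))
  expected <- expected + convP(3, w, cfg$outChannels)
  expect_equal(parameterCount(m), expected)
})

test_that("the heatmap loss is a masked per-pixel mean square", {
  p <- array(0, c(8, 8, 2, 1)); t <- p
  expect_equal(heatmapLoss(p, t)$loss, 0)
  t2 <- p; t2[, , 1, 1] <- 3   # constant offset c on a single visible channel
  vis1 <- matrix(c(TRUE, FALSE), 2, 1)
  expect_equal(heatmapLoss(p, t2, vis1)$loss, 9)
  # masking removes exactly the masked channel's contribution
  set.seed(1)
  pr <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  tr <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  full <- heatmapLoss(pr, tr)$loss
  only1 <- heatmapLoss(pr, tr, matrix(c(TRUE, FALSE), 2, 1))$loss
  only2 <- heatmapLoss(pr, tr, matrix(c(FALSE, TRUE), 2, 1))$loss
  expect_equal(full, (only1 + only2) / 2, tolerance = 1e-12)
  # invisible channels receive exactly zero gradient
  g <- heatmapLoss(pr, tr, matrix(c(TRUE, FALSE), 2, 1))$grad
  expect_true(all(g[, , 2, 1] == 0))
  expect_warning(heatmapLoss(pr, tr, matrix(FALSE, 2, 1)), "invisible")
})

test_that("the coordinate loss averages squared components over visible landmarks", {
  p <- array(0, c(1, 2, 1)); t <- p
  expect_equal(coordinateLoss(p, t)$loss, 0)
  t[1, , 1] <- c(3, 4)
  expect_equal(coordinateLoss(p, t)$loss, 12.5)
  # an invisible landmark is excluded exactly
  p2 <- array(0, c(2, 2, 1)); t2 <- p2
  t2[1, , 1] <- c(3, 4); t2[2, , 1] <- c(100, 100)
  vis <- matrix(c(TRUE, FALSE), 2, 1)
  expect_equal(coordinateLoss(p2, t2, vis)$loss, 12.5)
  expect_true(all(coordinateLoss(p2, t2, vis)$grad[2, , 1] == 0))
})

test_that("backpropagation matches finite differences through the network", {
  set.seed(42)
  cfg <- unetConfig(levels = 2L, width = 3L, outChannels = 2L, dropout = 0,
                    outputScale = 1)
  m <- unetInit(cfg, seed = 7)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  tgt <- array(rnorm(16 * 16 * 2 * 2), c(16, 16, 2, 2))
  fw <- unetForward(m, x, training = TRUE)
  hl <- heatmapLoss(fw$out, tgt)
  bw <- unetBackward(m, fw$cache, hl$grad)
  num <- function(path, idx) {
    eps <- 1e-5
    up <- m; up$params[[path]][idx] <- up$params[[path]][idx] + eps
    dn <- m; dn$params[[path]][idx] <- dn$params[[path]][idx] - eps
    (heatmapLoss(unetForward(up, x, training = TRUE)$out, tgt)$loss -
     heatmapLoss(unetForward(dn, x, training = TRUE)$out, tgt)$loss) / (2 * eps)
  }
  for (ch in list(list(c("enc1_c1", "w"), 5), list(c("enc2_c2", "gamma"), 2),
                  list(c("dec1_c1", "w"), 20), list(c("final", "w"), 3))) {
    an <- bw$grads[[ch[[1]]]][ch[[2]]]
    expect_equal(an, num(ch[[1]], ch[[2]]), tolerance = 1e-4)
  }
})

test_that("gradients of invisible-landmark targets are exactly zero end to end", {
  set.seed(3)
  cfg <- unetConfig(levels = 1L, width = 2L, outChannels = 3L, dropout = 0,
                    outputScale = 1)
  m <- unetInit(cfg, seed = 1)
  x <- array(rnorm(8 * 8), c(8, 8, 1, 1))
  tgt <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
  vis <- matrix(c(TRUE, FALSE, TRUE), 3, 1)
  fw <- unetForward(m, x, training = TRUE)
  hl <- heatmapLoss(fw$out, tgt, vis)
  # perturbing the invisible channel's target leaves loss and grads unchanged
  tgt2 <- tgt; tgt2[, , 2, 1] <- tgt2[, , 2, 1] + 100
  hl2 <- heatmapLoss(fw$out, tgt2, vis)
  expect_equal(hl$loss, hl2$loss)
  expect_equal(hl$grad, hl2$grad)
})
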