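test_that("blob extraction finds rendered peaks and applies the peak ranking", {
  h <- renderTarget(c(40, 40), c(128, 128), blobConfig(gamma = 1)) +
       renderTarget(c(90, 90), c(128, 128), blobConfig(gamma = 0.8))
  cand <- extractCandidates(h)
  expect_gte(nrow(cand), 2)
  top2 <- cand[1:2, ]
  d1 <- min(sqrt((top2$u - 40)^2 + (top2$v - 40)^2))
  d2 <- min(sqrt((top2$u - 90)^2 + (top2$v - 90)^2))
  expect_lt(d1, 1.5); expect_lt(d2, 1.5)
  expect_true(all(diff(cand$peak) <= 0))
  expect_equal(sum(cand$norm), 1, tolerance = 0.05)
})

test_that("normalized peaks follow the ratio formula and the threshold", {
  # peak-ratio arithmetic: peaks 0.98 and 0.01 normalize to 0.9899 / 0.0101
  n <- c(0.98, 0.01) / sum(c(0.98, 0.01))
  expect_equal(round(n, 4), c(0.9899, 0.0101))
  # values below the 0.015 threshold are discarded by the stated rule
  n2 <- c(1.0, 0.01) / sum(c(1.0, 0.01))
  expect_lt(n2[2], 0.015)
  h <- renderTarget(c(30, 30), c(96, 96), blobConfig(gamma = 1)) +
       renderTarget(c(70, 70), c(96, 96), blobConfig(gamma = 0.005))
  cand <- extractCandidates(h)
  expect_true(all(sqrt((cand$u - 70)^2 + (cand$v - 70)^2) > 3))
})

test_that("t-distribution fits recover simulated edge distances", {
  set.seed(31)
  x <- 40 + 2 * rt(500, df = 5)
  fit <- optim(c(median(x), log(mad(x)), log(5)),
               gaffa:::tNegLogLik, x = x, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  expect_lt(abs(fit$par[1] - 40), 0.5)
  expect_lt(abs(exp(fit$par[2]) - 2), 0.5)
})

test_that("edge statistics flag rigid data and pick three reference edges", {
  topo <- defaultHandTopology()
  base <- handTemplate()
  lms <- lapply(1:6, function(k) LandmarkSet(base, imageId = paste0("r", k)))
  es <- fitEdgeStats(lms, topo)
  expect_equal(length(es$referenceEdges), 3L)
  expect_true(all(es$edges$sigma <= 0.05))   # near the scale floor
  expect_error(fitEdgeStats(lms[1:2], topo), "at least 3")
  f <- tempfile(fileext = ".json")
  writeEdgeStats(es, f)
  back <- readEdgeStats(f)
  expect_equal(back$edges$mu, es$edges$mu, tolerance = 1e-9)
})

test_that("loopy belief propagation is exact on trees", {
  set.seed(9)
  for (rep in 1:3) {
    nV <- 6
    un <- lapply(sample(2:4, nV, replace = TRUE), function(k) log(runif(k)))
    edges <- cbind(2:nV, vapply(2:nV, function(v) sample(v - 1, 1), integer(1)))
    pots <- lapply(seq_len(nrow(edges)), function(k) {
      a <- edges[k, 1]; b <- edges[k, 2]
      list(a = a, b = b,
           logpsi = matrix(log(runif(length(un[[a]]) * length(un[[b]]))),
                           length(un[[a]]), length(un[[b]])))
    })
    sol <- gaffa:::lbpSumProduct(un, pots, maxIter = 200, damping = 0)
    bf <- bruteForceMarginals(un, pots)
    for (i in seq_len(nV))
      expect_lt(max(abs(exp(sol$beliefs[[i]]) - bf[[i]])), 1e-6)
    expect_true(sol$converged)
  }
})

test_that("single candidates pass through the assignment unchanged", {
  topo <- chainTopology3()
  cand <- lapply(list(c(3, 4), c(10, 11), c(20, 18)), function(p)
    data.frame(u = p[1], v = p[2], peak = 1, norm = 1))
  base <- rbind(c(3, 4), c(10, 11), c(20, 18))
  lms <- lapply(1:5, function(k) LandmarkSet(base + rnorm(6, 0, 0.2)))
  es <- fitEdgeStats(lms, topo)
  sol <- solveMrf(cand, es, topo)
  expect_equal(sol$picked, c(1L, 1L, 1L))
  expect_equal(sol$coords[, "u"], base[, 1])
})

test_that("an anatomically impossible high-peak candidate is rejected", {
  # five-landmark chain with consistent spacing; landmark 3 has a planted
  # far-away candidate with the higher peak
  topo <- Topology(5, cbind(1:4, 2:5))
  set.seed(17)
  base <- cbind(seq(10, 50, by = 10), rep(20, 5))
  lms <- lapply(1:40, function(k) LandmarkSet(base + rnorm(10, 0, 0.5)))
  es <- fitEdgeStats(lms, topo)
  cand <- lapply(1:5, function(i) {
    if (i == 3)
      data.frame(u = c(95, base[3, 1]), v = c(90, base[3, 2]),
                 peak = c(1.0, 0.8), norm = c(1.0, 0.8) / 1.8)
    else data.frame(u = base[i, 1], v = base[i, 2], peak = 1, norm = 1)
  })
  sol <- solveMrf(cand, es, topo)
  expect_equal(sol$picked[3], 2L)
  expect_equal(unname(sol$coords[3, ]), unname(base[3, ]))
})

test_that("ratio costs are invariant to a global coordinate rescaling", {
  topo <- Topology(4, cbind(1:3, 2:4))
  set.seed(23)
  base <- cbind(c(5, 15, 25, 35), c(10, 12, 9, 11))
  lms <- lapply(1:30, function(k) LandmarkSet(base + rnorm(8, 0, 0.3)))
  es <- fitEdgeStats(lms, topo)
  mkCand <- function(s) lapply(1:4, function(i) {
    data.frame(u = s * c(base[i, 1], base[i, 1] + 3),
               v = s * c(base[i, 2], base[i, 2] - 2),
               peak = c(1, 0.7), norm = c(1, 0.7) / 1.7)
  })
  # the rescaled-distance term d * mu_ref / d_ref is unchanged under u -> c u
  d1 <- gaffa:::ratioLogDens(10, es$edges[1, ], dRef = c(9, 11, 10),
                             muRef = es$edges$mu[es$referenceEdges])
  d2 <- gaffa:::ratioLogDens(10 * 3, es$edges[1, ], dRef = 3 * c(9, 11, 10),
                             muRef = es$edges$mu[es$referenceEdges])
  expect_equal(d1, d2, tolerance = 1e-12)
  s1 <- solveMrf(mkCand(1), es, topo)
  expect_true(all(is.finite(s1$coords)))
})

test_that("heatmap-stack refinement falls back to argmax when blobless", {
  topo <- chainTopology3()
  base <- rbind(c(6, 7), c(16, 15), c(25, 24))
  lms <- lapply(1:6, function(k) LandmarkSet(base + rnorm(6, 0, 0.3)))
  es <- fitEdgeStats(lms, topo)
  grids <- array(0, c(32, 32, 3))
  for (i in 1:3) grids[, , i] <- renderTarget(base[i, ], c(32, 32),
                                              blobConfig(gamma = 1))
  co <- gmRefine(grids, es, topo)
  expect_lt(max(abs(co - base)), 1.5)
})
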