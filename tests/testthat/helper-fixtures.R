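# Shared fixtures: tiny topologies, synthetic prior banks and independent
# oracle implementations used by several test files.

# three-landmark chain 1 - 2 - 3 (no global set)
chainTopology3 <- function() Topology(3, rbind(c(1, 2), c(2, 3)))

# a ConditionalPrior with an arbitrary grid (for layer plumbing tests)
makePrior <- function(i, j, grid, frame, gridStep = 1L) {
  new("ConditionalPrior", pair = as.integer(c(i, j)), grid = grid,
      nComponents = 1L, frame = as.integer(frame),
      gridStep = as.integer(gridStep))
}

# bank with random positive grids for every message pair of a topology
randomBank <- function(topology, frame, gridStep = 1L, seed = 1) {
  set.seed(seed)
  kd <- 2L * as.integer(frame) %/% gridStep
  priors <- list()
  mp <- messagePairs(topology)
  for (r in seq_len(nrow(mp)))
    priors[[mp$key[r]]] <- makePrior(mp$i[r], mp$j[r],
                                     matrix(abs(rnorm(kd[1] * kd[2])), kd[1], kd[2]),
                                     frame, gridStep)
  new("PriorBank", priors = priors, frame = as.integer(frame),
      topology = topology)
}

# bank whose kernels are (near-)delta displacement priors: p(i|j) has all its
# mass at centre + disp[[key]], so a message shifts the sender's map exactly.
# The amplitude must sit well above the softplus floor of the energy layer
# for the prior to dominate the message background.
deltaBank <- function(topology, frame, disp, amplitude = 50) {
  H <- frame[1]; W <- frame[2]
  priors <- list()
  mp <- messagePairs(topology)
  for (r in seq_len(nrow(mp))) {
    key <- mp$key[r]
    g <- matrix(0, 2 * H, 2 * W)
    d <- disp[[key]]
    g[H + 1 + d[2], W + 1 + d[1]] <- amplitude  # centre (0-based (W,H)) + d
    priors[[key]] <- makePrior(mp$i[r], mp$j[r], g, frame, 1L)
  }
  new("PriorBank", priors = priors, frame = as.integer(frame),
      topology = topology)
}

# literal nested-loop transcription of the refined marginal-energy equation,
# independent of the layer implementation (flat resolution, inference-mode
# batch normalization with identity running statistics).
refineOracle <- function(heat, bank, topology, beta = 5, eps = 1e-6) {
  d <- dim(heat)
  sp <- function(x) log(1 + exp(beta * x)) / beta
  bnid <- function(x) x / sqrt(1 + 1e-8)
  out <- array(0, d)
  for (i in seq_len(d[3])) {
    me <- log(sp(bnid(heat[, , i]) + eps))
    S <- matrix(0, d[1], d[2])
    for (j in extendedNeighborhood(topology, i)) {
      K <- sp(bankPrior(bank, i, j)@grid)
      pj <- sp(bnid(heat[, , j]))
      conv <- messageConvolve(pj, K, "direct")
      S <- S + log(conv + sp(matrix(eps, d[1], d[2])) + eps)
    }
    out[, , i] <- me + S
  }
  out
}

# exhaustive sum-product marginals by enumerating all assignments
bruteForceMarginals <- function(unaries, pairPot) {
  doms <- lapply(unaries, seq_along)
  grid <- expand.grid(doms)
  p <- apply(grid, 1, function(a) {
    s <- sum(vapply(seq_along(unaries), function(i) unaries[[i]][a[i]],
                    numeric(1)))
    for (e in pairPot) s <- s + e$logpsi[a[e$a], a[e$b]]
    exp(s)
  })
  p <- p / sum(p)
  lapply(seq_along(unaries), function(i)
    vapply(doms[[i]], function(v) sum(p[grid[[i]] == v]), numeric(1)))
}
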