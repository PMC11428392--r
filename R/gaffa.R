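# Differentiable one-iteration sum-product refinement in log-energy space.
#
# For landmark i with extended neighborhood N_i, the refined marginal energy
# is
#   me^_i = me_i + sum_{j in N_i} log( sp(p_{i|j}) (*) sp(p_j) + sp(b_{j->i}) + eps )
# with me_i = log sp(p_i + eps), sp = softplus_beta, (*) true convolution of
# the double-size conditional kernel, p_j the (batch-normalized, bicubic
# downsampled) localization heatmap of j, and b_{j->i} a learnable bias grid.
# The sum is computed at a downsampled working resolution and bicubic
# upsampled before the addition with the full-resolution me_i. No conversion
# back from log space is performed: the maximum location is unchanged by the
# monotone log, and coordinates are decoded with a softmax soft-argmax
# (linear expected-coordinate decoding of the exponentiated energies).

#' GAFFA refinement configuration
#'
#' @param beta softplus inverse temperature (default 5).
#' @param epsilon energy floor added before logs and used to initialize the
#'   bias grids (default 1e-6).
#' @param downFactor power-of-two divisor of the localization frame giving
#'   the message working resolution (default 4: 256 -> 64 working, 128
#'   kernels).
#' @param kernelStoreFactor additional power-of-two factor at which the
#'   conditional kernels are stored relative to the message resolution
#'   (default 2: kernels are kept coarse to limit learnable parameters and
#'   bicubic-upsampled to twice the working frame before each convolution).
#' @return a config list.
#' @export
gaffaConfig <- function(beta = 5, epsilon = 1e-6, downFactor = 4L,
                        kernelStoreFactor = 2L) {
  stopifnot(beta > 0, epsilon > 0,
            downFactor >= 1, bitwAnd(downFactor, downFactor - 1L) == 0,
            kernelStoreFactor >= 1,
            bitwAnd(kernelStoreFactor, kernelStoreFactor - 1L) == 0)
  list(beta = beta, epsilon = epsilon, downFactor = as.integer(downFactor),
       kernelStoreFactor = as.integer(kernelStoreFactor))
}

#' Ordered message pairs of a topology
#'
#' Every (receiver i, sender j) with j in the extended neighborhood of i.
#' @param topology a [Topology-class].
#' @return data.frame with columns i, j, key ("i|j").
#' @export
messagePairs <- function(topology) {
  rows <- do.call(rbind, lapply(seq_len(topology@nLandmarks), function(i) {
    js <- extendedNeighborhood(topology, i)
    if (!length(js)) return(NULL)
    cbind(i = i, j = js)
  }))
  if (is.null(rows))
    return(data.frame(i = integer(0), j = integer(0), key = character(0)))
  data.frame(i = rows[, "i"], j = rows[, "j"],
             key = paste0(rows[, "i"], "|", rows[, "j"]))
}

#' Unary marginal energy of a heatmap
#'
#' Elementwise \eqn{\log \mathrm{softplus}_\beta(p + \epsilon)}; computed at
#' full localization resolution so the initial accuracy is preserved.
#'
#' @param p heatmap values (any shape).
#' @param beta,epsilon see [gaffaConfig()].
#' @return same shape as `p`.
#' @export
unaryEnergy <- function(p, beta = 5, epsilon = 1e-6) {
  x <- p + epsilon
  # log softplus_beta(x): for very negative x, softplus underflows to zero in
  # double arithmetic although the true value is ~ exp(beta x)/beta; switch to
  # that asymptote to stay finite for any finite input
  out <- log(softplusBeta(x, beta))
  low <- beta * x < -30
  out[low] <- beta * x[low] - log(beta)
  out
}

#' Initialize GAFFA parameters from a prior bank
#'
#' The conditional kernels are initialized with the rasterized mixture
#' densities (held at the coarse storage resolution) and remain learnable;
#' every bias grid starts at `epsilon`; the heatmap batch normalization
#' starts as the identity.
#'
#' @param bank a [PriorBank-class] (its grid step must equal
#'   `downFactor * kernelStoreFactor`, or its grids are resampled).
#' @param topology a [Topology-class].
#' @param frame localization frame (H, W).
#' @param cfg a [gaffaConfig()].
#' @return list(params, buffers, pairs, frame, cfg).
#' @export
gaffaInit <- function(bank, topology, frame, cfg = gaffaConfig()) {
  frame <- as.integer(frame)
  step <- cfg$downFactor * cfg$kernelStoreFactor
  kd <- 2L * frame %/% step              # stored kernel dims
  wd <- frame %/% cfg$downFactor         # working frame dims
  pairs <- messagePairs(topology)
  kernels <- list(); biases <- list()
  for (r in seq_len(nrow(pairs))) {
    pr <- bankPrior(bank, pairs$i[r], pairs$j[r])
    g <- pr@grid
    if (!all(dim(g) == kd))
      g <- matrix(resizeBicubic(g, kd[1], kd[2]), kd[1], kd[2])
    kernels[[pairs$key[r]]] <- g
    biases[[pairs$key[r]]] <- matrix(cfg$epsilon, wd[1], wd[2])
  }
  L <- topology@nLandmarks
  list(params = list(kernels = kernels, biases = biases,
                     bnGamma = rep(1, L), bnBeta = numeric(L)),
       buffers = list(rm = numeric(L), rv = rep(1, L)),
       pairs = pairs, frame = frame, cfg = cfg)
}

# softmax soft-argmax over each channel/batch slice (fused in C++); returns
# coords and the probability array for backprop.
dsntFwd <- function(mehat) {
  r <- cpp_dsnt_fwd(mehat)
  list(coords = r$coords, p = r$p)
}

dsntBwd <- function(fw, gcoords) {
  cpp_dsnt_bwd(fw$p, fw$coords, gcoords)
}

#' GAFFA forward pass
#'
#' Batch-normalizes the localization heatmaps, downsamples them bicubically
#' to the working resolution, convolves each sender heatmap with the
#' (softplus-rectified, bicubic-upsampled) conditional kernel of every
#' message pair, accumulates log-message sums per receiver, upsamples the
#' sums back to full resolution, adds the full-resolution unary energy and
#' decodes subpixel coordinates with the soft-argmax.
#'
#' @param ga state from [gaffaInit()].
#' @param heat localization heatmaps [H, W, L, B].
#' @param training logical: batch statistics (TRUE) or running statistics.
#' @param keepEnergies include the marginal-energy stack in the result
#'   (default TRUE; the training loop disables it to save memory traffic).
#' @return list(mehat, coords, cache, buffers).
#' @export
gaffaForward <- function(ga, heat, training = FALSE, keepEnergies = TRUE) {
  cfg <- ga$cfg; pairs <- ga$pairs
  d <- dim(heat); H <- d[1]; W <- d[2]; L <- d[3]; B <- d[4]
  h <- H %/% cfg$downFactor; w <- W %/% cfg$downFactor
  P <- nrow(pairs)
  bn <- bnActFwd(heat, list(gamma = ga$params$bnGamma, beta = ga$params$bnBeta),
                 ga$buffers, training, slope = 1)
  p <- bn$y
  if (P == 0) {
    mehat <- unaryEnergy(p, cfg$beta, cfg$epsilon)
    fw <- dsntFwd(mehat)
    return(list(mehat = if (keepEnergies) mehat else NULL,
                coords = fw$coords, buffers = bn$buf,
                cache = list(bn = bn$cache, p = p, dsnt = fw, d = d,
                             hw = c(h, w))))
  }
  pds <- if (cfg$downFactor > 1) resizeBicubic(p, h, w) else p
  sph <- softplusBeta(pds, cfg$beta)
  # stack stored kernels / biases and process them in one batched pass
  kst <- array(unlist(ga$params$kernels, use.names = FALSE),
               c(dim(ga$params$kernels[[1]]), P, 1))
  kup <- if (cfg$kernelStoreFactor > 1)
    resizeBicubic(kst, 2 * h, 2 * w) else kst
  dim(kup) <- c(2 * h, 2 * w, P)
  spk <- softplusBeta(kup, cfg$beta)
  bst <- array(unlist(ga$params$biases, use.names = FALSE), c(h, w, P))
  spb <- softplusBeta(bst, cfg$beta)
  msg <- cpp_msg_all_fwd(sph, spk, spb, pairs$i, pairs$j, cfg$epsilon)
  Sup <- if (cfg$downFactor > 1) resizeBicubic(msg$S, H, W) else msg$S
  mehat <- cpp_me_fwd(p, Sup, cfg$beta, cfg$epsilon)
  fw <- dsntFwd(mehat)
  list(mehat = if (keepEnergies) mehat else NULL,
       coords = fw$coords, buffers = bn$buf,
       cache = list(bn = bn$cache, p = p, pds = pds, sph = sph, spk = spk,
                    kup = kup, bst = bst, inners = msg$inners, dsnt = fw,
                    d = d, hw = c(h, w)))
}

#' GAFFA backward pass
#'
#' @param ga state from [gaffaInit()].
#' @param cache forward cache.
#' @param gcoords gradient w.r.t. decoded coordinates [L, 2, B] (or NULL).
#' @param gmehat optional extra gradient w.r.t. the marginal energies.
#' @return list(grads (kernels, biases, bnGamma, bnBeta), gheat).
#' @export
gaffaBackward <- function(ga, cache, gcoords = NULL, gmehat = NULL) {
  cfg <- ga$cfg; pairs <- ga$pairs
  d <- cache$d; H <- d[1]; W <- d[2]; L <- d[3]; B <- d[4]
  h <- cache$hw[1]; w <- cache$hw[2]
  P <- nrow(pairs)
  gme <- if (!is.null(gcoords)) dsntBwd(cache$dsnt, gcoords) else array(0, d)
  if (!is.null(gmehat)) gme <- gme + gmehat
  if (P == 0) {
    gp <- cpp_me_bwd(cache$p, gme, cfg$beta, cfg$epsilon)
    bb <- bnActBwd(gp, cache$bn)
    return(list(grads = list(kernels = list(), biases = list(),
                             bnGamma = bb$ggamma, bnBeta = bb$gbeta),
                gheat = bb$gz))
  }
  # me^ = me + Sup: both branches receive gme
  gS <- if (cfg$downFactor > 1) resizeBicubicBwd(gme, h, w) else gme
  mb <- cpp_msg_all_bwd(cache$sph, cache$spk, gS, cache$inners,
                        pairs$i, pairs$j)
  gkup <- mb$gkup * softplusBetaGrad(cache$kup, cfg$beta)
  kd <- dim(ga$params$kernels[[1]])
  gkst <- if (cfg$kernelStoreFactor > 1) {
    dim(gkup) <- c(2 * h, 2 * w, P, 1)
    resizeBicubicBwd(gkup, kd[1], kd[2])
  } else gkup
  dim(gkst) <- c(kd[1], kd[2], P)
  gbst <- mb$gbias * softplusBetaGrad(cache$bst, cfg$beta)
  gkern <- stats::setNames(lapply(seq_len(P), function(r)
    matrix(gkst[, , r], kd[1], kd[2])), pairs$key)
  gbias <- stats::setNames(lapply(seq_len(P), function(r)
    matrix(gbst[, , r], h, w)), pairs$key)
  gpds <- mb$gsph * softplusBetaGrad(cache$pds, cfg$beta)
  gp <- if (cfg$downFactor > 1) resizeBicubicBwd(gpds, H, W) else gpds
  gp <- gp + cpp_me_bwd(cache$p, gme, cfg$beta, cfg$epsilon)
  bb <- bnActBwd(gp, cache$bn)
  list(grads = list(kernels = gkern, biases = gbias,
                    bnGamma = bb$ggamma, bnBeta = bb$gbeta),
       gheat = bb$gz)
}

#' Refine a heatmap stack with the sum-product layer
#'
#' Convenience inference wrapper: initializes the layer from a prior bank
#' (biases at their epsilon floor, batch normalization at its identity
#' initialization unless a trained state is supplied) and runs one forward
#' pass on a single image's heatmaps.
#'
#' @param stack a [HeatmapStack-class] or H x W x L array.
#' @param bank a [PriorBank-class].
#' @param topology a [Topology-class].
#' @param cfg a [gaffaConfig()].
#' @param ga optional trained state from [gaffaInit()] (overrides
#'   `bank`/`cfg`).
#' @return list(energies = [HeatmapStack-class] of marginal energies,
#'   coords = L x 2 matrix of refined (u, v) coordinates).
#' @export
gaffaRefine <- function(stack, bank = NULL, topology = NULL,
                        cfg = gaffaConfig(), ga = NULL) {
  grids <- if (is(stack, "HeatmapStack")) stack@grids else stack
  d <- dim(grids)
  if (is.null(ga)) {
    if (is.null(bank) || is.null(topology))
      stop("configuration error: gaffaRefine needs a prior bank and topology ",
           "(or a prepared state)")
    ga <- gaffaInit(bank, topology, d[1:2], cfg)
  }
  fw <- gaffaForward(ga, array(grids, c(d[1], d[2], d[3], 1)), training = FALSE)
  co <- matrix(fw$coords[, , 1], d[3], 2)
  colnames(co) <- c("u", "v")
  list(energies = HeatmapStack(array(fw$mehat, d[1:3])), coords = co)
}

#' Export marginal-energy heatmaps for visualization
#'
#' Writes one min-max scaled PNG per landmark channel.
#' @param energies a [HeatmapStack-class] of marginal energies.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
writeEnergyMaps <- function(energies, dir, prefix = "energy") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- dim(energies@grids)[3]
  for (i in seq_len(L))
    writeHeatmapPNG(heatmapChannel(energies, i),
                    file.path(dir, sprintf("%s_l%02d.png", prefix, i)))
  invisible(dir)
}
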