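# SpatialConfiguration-Net refinement head: a coarse spatial-filter branch
# whose output multiplies the local localization heatmaps elementwise.

#' SCN head configuration
#'
#' Three successive convolutions with large kernels (7 x 7, 128 feature
#' maps) operating in a heavily downsampled image space without further
#' internal downsampling, batch normalization before each activation; the
#' filter output is bilinearly upsampled to full resolution and combined
#' with the local heatmaps by an elementwise (Hadamard) product.
#'
#' @param nLayers number of convolutions (default 3).
#' @param kernel odd kernel size (default 7).
#' @param maps feature maps of the hidden convolutions (default 128).
#' @param downFactor power-of-two reduction into the spatial component
#'   (average pooling; default 4).
#' @param leakySlope activation slope for the hidden layers.
#' @return config list.
#' @export
scnConfig <- function(nLayers = 3L, kernel = 7L, maps = 128L, downFactor = 4L,
                      leakySlope = 0.1) {
  stopifnot(kernel %% 2 == 1, maps >= 1, nLayers >= 1,
            downFactor >= 1, bitwAnd(downFactor, downFactor - 1L) == 0)
  list(nLayers = as.integer(nLayers), kernel = as.integer(kernel),
       maps = as.integer(maps), downFactor = as.integer(downFactor),
       leakySlope = leakySlope)
}

#' Initialize an SCN head
#'
#' Hidden layers map L -> maps -> ... -> maps; the final convolution maps
#' back to L channels and stays linear so the learned spatial filter can
#' freely scale the local heatmaps.
#'
#' @param cfg an [scnConfig()].
#' @param nLandmarks number of heatmap channels L.
#' @param seed RNG seed.
#' @return model list(params, buffers, cfg).
#' @export
scnInit <- function(cfg = scnConfig(), nLandmarks = 37L, seed = 1L) {
  withSeed(seed, {
    params <- list(); buffers <- list()
    cins <- c(nLandmarks, rep(cfg$maps, cfg$nLayers - 1L))
    couts <- c(rep(cfg$maps, cfg$nLayers - 1L), nLandmarks)
    for (l in seq_len(cfg$nLayers)) {
      nm <- sprintf("sc%d", l)
      params[[nm]] <- newConvBlockParams(cfg$kernel, cins[l], couts[l], cfg$leakySlope)
      buffers[[nm]] <- list(rm = numeric(couts[l]), rv = rep(1, couts[l]))
    }
    list(cfg = cfg, params = params, buffers = buffers, nLandmarks = nLandmarks)
  })
}

#' SCN forward pass
#'
#' Downsamples the local heatmaps by average pooling, runs the convolution
#' stack (the last layer linear after batch normalization), upsamples the
#' spatial filter bilinearly to full resolution and returns the elementwise
#' product with the local heatmaps.
#'
#' @param model from [scnInit()].
#' @param local localization heatmaps [H, W, L, B].
#' @param training logical.
#' @return list(out, filter, cache, buffers).
#' @export
scnForward <- function(model, local, training = FALSE) {
  cfg <- model$cfg
  h <- local
  npool <- as.integer(log2(cfg$downFactor))
  for (k in seq_len(npool)) h <- cpp_avgpool2_fwd(h)
  caches <- list(poolIn = dim(local), npool = npool)
  buf <- model$buffers
  for (l in seq_len(cfg$nLayers)) {
    nm <- sprintf("sc%d", l)
    if (l < cfg$nLayers) {
      r <- convBlockFwd(h, model$params[[nm]], buf[[nm]], cfg$kernel, training,
                        cfg$leakySlope, dropout = 0)
      h <- r$y; buf[[nm]] <- r$buf; caches[[nm]] <- r$cache
    } else {
      # final layer: conv + batch norm, linear activation
      z <- cpp_conv2d_fwd(h, model$params[[nm]]$w, model$params[[nm]]$b,
                          cfg$kernel, cfg$kernel)
      bn <- bnActFwd(z, model$params[[nm]], buf[[nm]], training, slope = 1)
      caches[[nm]] <- list(x = h, w = model$params[[nm]]$w, k = cfg$kernel,
                           bn = bn$cache)
      h <- bn$y; buf[[nm]] <- bn$buf
    }
  }
  for (k in seq_len(npool)) h <- cpp_up2_bilinear_fwd(h)
  out <- local * h
  list(out = out, filter = h,
       cache = if (training) c(caches, list(local = local, filter = h)) else NULL,
       buffers = buf)
}

#' SCN backward pass
#'
#' @param model from [scnInit()].
#' @param cache forward cache.
#' @param gout gradient w.r.t. the product output.
#' @return list(grads, glocal).
#' @export
scnBackward <- function(model, cache, gout) {
  cfg <- model$cfg
  glocal <- gout * cache$filter
  g <- gout * cache$local
  for (k in seq_len(cache$npool)) g <- cpp_up2_bilinear_bwd(g)
  grads <- list()
  for (l in rev(seq_len(cfg$nLayers))) {
    nm <- sprintf("sc%d", l)
    if (l < cfg$nLayers) {
      r <- convBlockBwd(g, cache[[nm]])
      grads[[nm]] <- list(w = r$gw, b = r$gb, gamma = r$ggamma, beta = r$gbeta)
      g <- r$gx
    } else {
      bb <- bnActBwd(g, cache[[nm]]$bn)
      cb <- cpp_conv2d_bwd(cache[[nm]]$x, cache[[nm]]$w, bb$gz,
                           cache[[nm]]$k, cache[[nm]]$k)
      grads[[nm]] <- list(w = cb$gw, b = cb$gb, gamma = bb$ggamma, beta = bb$gbeta)
      g <- cb$gx
    }
  }
  d <- cache$poolIn
  for (k in seq_len(cache$npool)) {
    up <- d[1] / 2^(cache$npool - k); upw <- d[2] / 2^(cache$npool - k)
    g <- cpp_avgpool2_bwd(g, as.integer(up), as.integer(upw))
  }
  glocal <- glocal + g
  list(grads = grads, glocal = glocal)
}
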