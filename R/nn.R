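# Minimal convolutional-network engine with explicit backpropagation.
# Feature maps are [H, W, C, B] arrays; convolution weights are
# (k*k*cin) x cout matrices (see src/kernels.cpp for the layout contract).

# ---- batch normalization (per channel over H, W, B) ----
# Fused with the (optional) leaky activation in C++; slope = 1 gives plain
# batch normalization.

bnActFwd <- function(z, p, buf, training, slope = 1) {
  r <- cpp_bnact_fwd(z, p$gamma, p$beta, buf$rm, buf$rv, training, slope,
                     0.1, 1e-5)
  list(y = r$y, buf = list(rm = r$rm, rv = r$rv),
       cache = list(xhat = r$xhat, invstd = r$invstd, gamma = p$gamma,
                    beta = p$beta, slope = slope, training = training))
}

bnActBwd <- function(g, cache) {
  cpp_bnact_bwd(g, cache$xhat, cache$invstd, cache$gamma, cache$beta,
                cache$slope, cache$training)
}

# ---- conv -> batch norm -> leaky ReLU -> dropout block ----

convBlockFwd <- function(x, p, buf, k, training, slope = 0.1, dropout = 0,
                         xcat = NULL) {
  z <- if (is.null(xcat)) cpp_conv2d_fwd(x, p$w, p$b, k, k)
       else cpp_conv2d_cat_fwd(x, xcat, p$w, p$b, k, k)
  bn <- bnActFwd(z, p, buf, training, slope)
  a <- bn$y
  cache <- list(x = x, xcat = xcat, w = p$w, k = k, bn = bn$cache, mask = NULL)
  if (training && dropout > 0) {
    mask <- (stats::runif(length(a)) >= dropout) / (1 - dropout)
    a <- a * mask
    cache$mask <- mask
  }
  list(y = a, buf = bn$buf, cache = cache)
}

convBlockBwd <- function(g, cache, needGx = TRUE) {
  if (!is.null(cache$mask)) g <- g * cache$mask
  bb <- bnActBwd(g, cache$bn)
  if (is.null(cache$xcat)) {
    cb <- cpp_conv2d_bwd(cache$x, cache$w, bb$gz, cache$k, cache$k, needGx)
    list(gx = cb$gx, gw = cb$gw, gb = cb$gb, ggamma = bb$ggamma,
         gbeta = bb$gbeta)
  } else {
    cb <- cpp_conv2d_cat_bwd(cache$x, cache$xcat, cache$w, bb$gz,
                             cache$k, cache$k)
    list(gx = cb$gxa, gxcat = cb$gxb, gw = cb$gw, gb = cb$gb,
         ggamma = bb$ggamma, gbeta = bb$gbeta)
  }
}

channelConcat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# ---- U-Net ----

#' U-Net configuration
#'
#' Encoder-decoder with two convolutions per level, each convolution followed
#' by batch normalization, leaky rectification (slope 0.1) and dropout;
#' average pooling 2 x 2 for downsampling and fixed bilinear upsampling in
#' the decoder; skip connections concatenated channel-wise, so the first
#' decoder convolution of each level expects `2 * width` input maps. The
#' final convolution maps to one heatmap per landmark.
#'
#' @param levels encoder/decoder levels (input H, W must be divisible by
#'   `2^levels`).
#' @param width channels per convolution (reference setting: 128).
#' @param inChannels input image channels.
#' @param outChannels output heatmaps (landmarks), default 37.
#' @param kernel convolution kernel size (odd).
#' @param leakySlope negative slope of the leaky rectifier.
#' @param dropout dropout rate after each activation (reference: 0.3).
#' @param outputScale fixed multiplier on the final convolution output,
#'   matched to the target blob peak so the convolution stack regresses
#'   order-one values regardless of the heatmap scaling factor.
#' @param finalKernel kernel size of the output convolution (default:
#'   `kernel`; 1 gives a cheap per-pixel readout).
#' @return a config list.
#' @export
unetConfig <- function(levels = 4L, width = 128L, inChannels = 1L,
                       outChannels = 37L, kernel = 3L, leakySlope = 0.1,
                       dropout = 0.3, outputScale = 1000,
                       finalKernel = kernel) {
  stopifnot(levels >= 1, width >= 1, kernel %% 2 == 1, finalKernel %% 2 == 1,
            outputScale > 0)
  list(levels = as.integer(levels), width = as.integer(width),
       inChannels = as.integer(inChannels), outChannels = as.integer(outChannels),
       kernel = as.integer(kernel), leakySlope = leakySlope, dropout = dropout,
       outputScale = outputScale, finalKernel = as.integer(finalKernel))
}

kaimingConv <- function(k, cin, cout, slope) {
  fan <- k * k * cin
  sd <- sqrt(2 / ((1 + slope^2) * fan))
  matrix(stats::rnorm(fan * cout, 0, sd), fan, cout)
}

newConvBlockParams <- function(k, cin, cout, slope) {
  list(w = kaimingConv(k, cin, cout, slope), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout))
}

#' Initialize a U-Net model
#'
#' @param cfg a [unetConfig()].
#' @param seed RNG seed for the Kaiming fan-in initialization.
#' @return model list with `params` (named), `buffers` (running batch-norm
#'   statistics) and `cfg`.
#' @export
unetInit <- function(cfg = unetConfig(), seed = 1L) {
  withSeed(seed, {
    k <- cfg$kernel; wdt <- cfg$width; sl <- cfg$leakySlope
    params <- list(); buffers <- list()
    addBlock <- function(name, cin, cout) {
      params[[name]] <<- newConvBlockParams(k, cin, cout, sl)
      buffers[[name]] <<- list(rm = numeric(cout), rv = rep(1, cout))
    }
    for (lv in seq_len(cfg$levels)) {
      addBlock(sprintf("enc%d_c1", lv), if (lv == 1) cfg$inChannels else wdt, wdt)
      addBlock(sprintf("enc%d_c2", lv), wdt, wdt)
    }
    for (lv in seq_len(cfg$levels)) {
      addBlock(sprintf("dec%d_c1", lv), 2L * wdt, wdt)
      addBlock(sprintf("dec%d_c2", lv), wdt, wdt)
    }
    # final layer starts near zero so the scaled output begins flat
    params$final <- list(w = kaimingConv(cfg$finalKernel, wdt, cfg$outChannels,
                                         sl) / cfg$outputScale,
                         b = numeric(cfg$outChannels))
    list(cfg = cfg, params = params, buffers = buffers)
  })
}

#' Number of learnable parameters of a model
#' @param model a model list with a `params` entry.
#' @return integer count.
#' @export
parameterCount <- function(model) {
  sum(vapply(rapply(model$params, length, how = "unlist"), identity, numeric(1)))
}

#' U-Net forward pass
#'
#' @param model from [unetInit()].
#' @param x input array [H, W, inChannels, B] (a plain H x W matrix is
#'   promoted to a single-image batch).
#' @param training logical; batch statistics + dropout when TRUE.
#' @return list(out = heatmaps [H, W, L, B], cache (when training), buffers).
#' @export
unetForward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  if (is.matrix(x)) x <- array(x, c(dim(x), 1, 1))
  d <- dim(x)
  if (d[1] %% 2^cfg$levels != 0 || d[2] %% 2^cfg$levels != 0)
    stop("input frame must be divisible by 2^levels = ", 2^cfg$levels)
  p <- model$params; buf <- model$buffers
  caches <- list(); skips <- list()
  h <- x
  for (lv in seq_len(cfg$levels)) {
    for (cn in c("c1", "c2")) {
      nm <- sprintf("enc%d_%s", lv, cn)
      r <- convBlockFwd(h, p[[nm]], buf[[nm]], cfg$kernel, training,
                        cfg$leakySlope, cfg$dropout)
      h <- r$y; buf[[nm]] <- r$buf; caches[[nm]] <- r$cache
    }
    skips[[lv]] <- h
    caches[[sprintf("pool%d", lv)]] <- dim(h)
    h <- cpp_avgpool2_fwd(h)
  }
  for (lv in rev(seq_len(cfg$levels))) {
    h <- cpp_up2_bilinear_fwd(h)
    nm <- sprintf("dec%d_c1", lv)
    r <- convBlockFwd(h, p[[nm]], buf[[nm]], cfg$kernel, training,
                      cfg$leakySlope, cfg$dropout, xcat = skips[[lv]])
    h <- r$y; buf[[nm]] <- r$buf; caches[[nm]] <- r$cache
    nm <- sprintf("dec%d_c2", lv)
    r <- convBlockFwd(h, p[[nm]], buf[[nm]], cfg$kernel, training,
                      cfg$leakySlope, cfg$dropout)
    h <- r$y; buf[[nm]] <- r$buf; caches[[nm]] <- r$cache
  }
  caches$finalx <- h
  out <- cpp_conv2d_fwd(h, p$final$w, p$final$b, cfg$finalKernel, cfg$finalKernel)
  if (cfg$outputScale != 1) out <- out * cfg$outputScale
  list(out = out, cache = if (training) caches else NULL, buffers = buf)
}

#' U-Net backward pass
#'
#' @param model the model.
#' @param cache forward cache (training mode).
#' @param gout gradient w.r.t. the output heatmaps.
#' @return list(grads (named like `model$params`), gx).
#' @export
unetBackward <- function(model, cache, gout) {
  cfg <- model$cfg
  grads <- list()
  if (cfg$outputScale != 1) gout <- gout * cfg$outputScale
  cb <- cpp_conv2d_bwd(cache$finalx, model$params$final$w, gout,
                       cfg$finalKernel, cfg$finalKernel)
  grads$final <- list(w = cb$gw, b = cb$gb)
  g <- cb$gx
  for (lv in seq_len(cfg$levels)) {
    nm <- sprintf("dec%d_c2", lv)
    r <- convBlockBwd(g, cache[[nm]])
    grads[[nm]] <- list(w = r$gw, b = r$gb, gamma = r$ggamma, beta = r$gbeta)
    g <- r$gx
    nm <- sprintf("dec%d_c1", lv)
    r <- convBlockBwd(g, cache[[nm]])
    grads[[nm]] <- list(w = r$gw, b = r$gb, gamma = r$ggamma, beta = r$gbeta)
    g <- cpp_up2_bilinear_bwd(r$gx)
    # gradient entering the encoder level via the skip path
    assign(sprintf("gskip%d", lv), r$gxcat)
  }
  # g now flows into the deepest pool; walk encoder levels top-down in reverse
  for (lv in rev(seq_len(cfg$levels))) {
    dpool <- cache[[sprintf("pool%d", lv)]]
    g <- cpp_avgpool2_bwd(g, dpool[1], dpool[2])
    g <- g + get(sprintf("gskip%d", lv))
    for (cn in c("c2", "c1")) {
      nm <- sprintf("enc%d_%s", lv, cn)
      needGx <- !(lv == 1 && cn == "c1")
      r <- convBlockBwd(g, cache[[nm]], needGx)
      grads[[nm]] <- list(w = r$gw, b = r$gb, gamma = r$ggamma, beta = r$gbeta)
      g <- r$gx
    }
  }
  list(grads = grads, gx = g)
}

# ---- losses ----

#' Heatmap mean-squared-error loss with visibility masking
#'
#' Mean squared difference over the pixels of visible-landmark channels only;
#' channels of landmarks transformed out of the frame contribute nothing (and
#' receive exactly zero gradient).
#'
#' @param pred,target [H, W, L, B] arrays.
#' @param visible L x B logical matrix (default: all visible).
#' @return list(loss, grad).
#' @export
heatmapLoss <- function(pred, target, visible = NULL) {
  d <- dim(pred)
  if (is.null(visible)) visible <- matrix(TRUE, d[3], d[4])
  if (sum(visible) == 0) {
    warning("all landmarks invisible: heatmap loss contributes zero")
    return(list(loss = 0, grad = array(0, d)))
  }
  vm <- matrix(as.numeric(visible), d[3], d[4])
  cpp_mse_loss(pred, target, vm)
}

#' Coordinate mean-squared-error loss with visibility masking
#'
#' Mean of squared coordinate-component differences over visible landmarks
#' (a single landmark offset by (3, 4) scores (9 + 16) / 2 = 12.5).
#'
#' @param pred,target [L, 2, B] arrays of (u, v) coordinates.
#' @param visible L x B logical matrix.
#' @return list(loss, grad).
#' @export
coordinateLoss <- function(pred, target, visible = NULL) {
  d <- dim(pred)
  if (is.null(visible)) visible <- matrix(TRUE, d[1], d[3])
  nvis <- sum(visible)
  if (nvis == 0) return(list(loss = 0, grad = array(0, d)))
  mask <- array(0, d)
  mask[, 1, ] <- visible; mask[, 2, ] <- visible
  diffs <- (pred - target) * mask
  N <- 2 * nvis
  list(loss = sum(diffs^2) / N, grad = 2 * diffs / N)
}

# ---- Adam optimizer over nested named parameter lists ----

flattenParams <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) out <- c(out, flattenParams(p[[nm]], key))
    else out[[key]] <- p[[nm]]
  }
  out
}

unflattenInto <- function(p, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    p[[path]] <- flat[[key]]
  }
  p
}

#' Adam optimizer state
#' @param params nested named parameter list.
#' @return optimizer state.
#' @export
adamInit <- function(params) {
  flat <- flattenParams(params)
  list(m = lapply(flat, function(x) x * 0), v = lapply(flat, function(x) x * 0),
       t = 0L)
}

#' One Adam step
#' @param params nested parameter list.
#' @param grads matching nested gradient list.
#' @param state from [adamInit()].
#' @param lr learning rate (reference: 1e-3).
#' @param beta1,beta2,eps Adam moment/stability constants.
#' @return list(params, state).
#' @export
adamStep <- function(params, grads, state, lr = 1e-3,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  fp <- flattenParams(params); fg <- flattenParams(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (key in names(fg)) {
    g <- fg[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    fp[[key]] <- fp[[key]] -
      lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
  }
  list(params = unflattenInto(params, fp), state = state)
}
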