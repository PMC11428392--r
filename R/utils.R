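#' Softplus with inverse temperature
#'
#' Smooth rectifier \eqn{\mathrm{softplus}_\beta(x) = \log(1 + e^{\beta x})/\beta},
#' strictly positive and monotone increasing. Used throughout the energy-space
#' refinement to keep convolution inputs positive.
#'
#' @param x numeric vector/array.
#' @param beta inverse temperature (> 0), default 5.
#' @return numeric of the same shape as `x`.
#' @export
softplusBeta <- function(x, beta = 5) {
  if (beta <= 0) stop("beta must be > 0")
  # overflow-safe: softplus(x) = max(x,0) + log1p(exp(-|beta x|))/beta
  pmax(x, 0) + log1p(exp(-abs(beta * x))) / beta
}

# derivative of softplusBeta: logistic sigmoid at beta*x
softplusBetaGrad <- function(x, beta = 5) {
  1 / (1 + exp(-beta * x))
}

# ---- resampling tap machinery ----

# Catmull-Rom cubic kernel (a = -0.5), the conventional bicubic kernel.
cubicKernel <- function(t, a = -0.5) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  i2 <- at > 1 & at < 2
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# 4-tap bicubic resampling taps for one axis.
# convention "area": output pixel o samples input coordinate
#   (o + 0.5) * in/out - 0.5  (pixel-area alignment, the common default)
# convention "corners": o samples o * (in-1)/(out-1) (endpoints map to endpoints)
resizeTaps <- function(outN, inN, convention = c("area", "corners")) {
  convention <- match.arg(convention)
  o <- seq_len(outN) - 1
  pos <- if (convention == "area") (o + 0.5) * (inN / outN) - 0.5
         else if (outN == 1) rep(0, 1) else o * (inN - 1) / (outN - 1)
  base <- floor(pos)
  idx <- outer(base, -1:2, `+`)
  w <- matrix(cubicKernel(pos - idx), outN, 4)
  w <- w / rowSums(w)
  idx <- pmin(pmax(idx, 0), inN - 1)
  list(idx = matrix(as.integer(idx), outN, 4), w = matrix(w, outN, 4))
}

# Bicubic resize of an [H, W, C, B] array (forward); linear operator.
resizeBicubic <- function(x, outH, outW, convention = "area") {
  d <- dim(x)
  if (length(d) == 2) { x <- array(x, c(d, 1, 1)); d <- dim(x) }
  r <- resizeTaps(outH, d[1], convention)
  cc <- resizeTaps(outW, d[2], convention)
  cpp_resize4_fwd(x, r$idx, r$w, cc$idx, cc$w)
}

# Transpose (adjoint) of resizeBicubic for backprop.
resizeBicubicBwd <- function(g, inH, inW, convention = "area") {
  d <- dim(g)
  r <- resizeTaps(d[1], inH, convention)
  cc <- resizeTaps(d[2], inW, convention)
  cpp_resize4_bwd(g, r$idx, r$w, cc$idx, cc$w, inH, inW)
}

# ---- 2-D convolution helpers for the message-passing layer ----

#' Convolve a heatmap with a double-size kernel
#'
#' True 2-D convolution of an \eqn{h \times w} map with a \eqn{2h \times 2w}
#' kernel whose origin sits at its centre pixel, cropped to the centred
#' \eqn{h \times w} window:
#' \deqn{out[y,x] = \sum_{p,q} map[p,q]\, K[h+y-p,\; w+x-q]}
#' (0-based indices). A kernel that is a discrete delta at displacement d from
#' its centre therefore shifts the map by exactly d.
#'
#' @param map numeric matrix (h x w).
#' @param kernel numeric matrix (2h x 2w).
#' @param method "fft" (Fourier-domain product), "gemm" (dense Toeplitz matrix
#'   through BLAS) or "direct" (literal nested-loop sum, slow; reference).
#' @return numeric h x w matrix.
#' @export
messageConvolve <- function(map, kernel, method = c("fft", "gemm", "direct")) {
  method <- match.arg(method)
  h <- nrow(map); w <- ncol(map)
  if (!all(dim(kernel) == c(2 * h, 2 * w)))
    stop("kernel must be exactly twice the map extent (", 2 * h, " x ", 2 * w, ")")
  if (method == "direct") {
    out <- matrix(0, h, w)
    for (y in 0:(h - 1)) for (x in 0:(w - 1)) {
      acc <- 0
      for (p in 0:(h - 1)) for (q in 0:(w - 1))
        acc <- acc + map[p + 1, q + 1] * kernel[h + y - p + 1, w + x - q + 1]
      out[y + 1, x + 1] <- acc
    }
    out
  } else if (method == "gemm") {
    arr <- array(map, c(h, w, 1))
    matrix(cpp_msgconv_fwd(arr, kernel), h, w)
  } else {
    # full linear convolution via FFT, cropped to the centred window
    P1 <- 3 * h - 1; P2 <- 3 * w - 1
    A <- matrix(0, P1, P2); A[1:h, 1:w] <- map
    B <- matrix(0, P1, P2); B[1:(2 * h), 1:(2 * w)] <- kernel
    full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (P1 * P2)
    full[(h + 1):(2 * h), (w + 1):(2 * w)]
  }
}

# ---- misc ----

# Deterministic sub-seed derivation, kept below 2^31.
deriveSeed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  acc <- 0
  for (p in parts) acc <- (acc * 69069 + as.double(p) + 1) %% 2147483647
  as.integer(acc)
}

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# 0-based coordinate grids for an H x W frame; (u, v) = (column, row).
coordGrids <- function(H, W) {
  list(u = matrix(rep(0:(W - 1), each = H), H, W),
       v = matrix(rep(0:(H - 1), W), H, W))
}

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
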