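# Target-heatmap rendering and coordinate decoding.

#' Blob configuration for target heatmaps
#'
#' @param sigma blob width in pixels (> 0, default 3).
#' @param gamma peak scaling factor (> 0, default 1000); large peaks keep the
#'   regression loss well away from numerical underflow.
#' @param family "gaussian" (\eqn{\gamma e^{-d^2/2\sigma^2}}) or "laplacian"
#'   (\eqn{\gamma e^{-d/\sigma}}), with d the Euclidean pixel distance to the
#'   landmark. Laplacian blobs concentrate more mass near the peak.
#' @return a validated config list.
#' @export
blobConfig <- function(sigma = 3, gamma = 1000, family = c("gaussian", "laplacian")) {
  if (!isScalarNumber(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!isScalarNumber(gamma) || gamma <= 0) stop("gamma must be > 0")
  list(sigma = sigma, gamma = gamma, family = match.arg(family))
}

#' Render a target heatmap for one landmark
#'
#' Places a blob whose peak coincides with the landmark; blobs are evaluated
#' over the whole frame (no radius cutoff), so a landmark outside the frame
#' leaves only its clipped tail (or an all-zero map when far away).
#'
#' @param landmark numeric (u, v) pixel position (may be subpixel or outside
#'   the frame).
#' @param frame integer (H, W).
#' @param cfg a [blobConfig()].
#' @return H x W numeric matrix.
#' @export
renderTarget <- function(landmark, frame, cfg = blobConfig()) {
  H <- frame[1]; W <- frame[2]
  if (H <= 0 || W <= 0) stop("frame must be positive")
  g <- coordGrids(H, W)
  d2 <- (g$u - landmark[1])^2 + (g$v - landmark[2])^2
  if (cfg$family == "gaussian") cfg$gamma * exp(-d2 / (2 * cfg$sigma^2))
  else cfg$gamma * exp(-sqrt(d2) / cfg$sigma)
}

#' Render the full target stack for a LandmarkSet
#'
#' Invisible landmarks get an all-zero channel.
#' @param landmarks a [LandmarkSet-class].
#' @param frame integer (H, W).
#' @param cfg a [blobConfig()].
#' @return a [HeatmapStack-class] with one channel per landmark.
#' @export
renderTargetStack <- function(landmarks, frame, cfg = blobConfig()) {
  co <- landmarkCoords(landmarks); vis <- landmarkVisible(landmarks)
  L <- nrow(co)
  grids <- array(0, c(frame[1], frame[2], L))
  for (i in seq_len(L)) if (vis[i]) grids[, , i] <- renderTarget(co[i, ], frame, cfg)
  HeatmapStack(grids)
}

#' Decode a heatmap by its intensity maximum
#'
#' Returns the integer pixel location of the highest intensity; ties are
#' broken by the first occurrence in row-major scan order (left-to-right, then
#' top-to-bottom).
#'
#' @param h numeric matrix.
#' @return numeric (u, v), 0-based.
#' @export
decodeArgmax <- function(h) {
  if (length(h) == 0) stop("empty heatmap")
  # row-major scan: transpose so which.max's column-major scan walks rows first
  k <- which.max(t(h)) - 1
  W <- ncol(h)
  c(u = k %% W, v = k %/% W)
}

#' Differentiable soft-argmax (DSNT) decoding
#'
#' Turns the heatmap into a spatial distribution and returns the expectation
#' of the 0-based pixel-coordinate grid under it. With `normalize = "linear"`
#' values are clamped at zero and divided by their sum (exact for
#' non-negative inputs: a one-hot map decodes to exactly that pixel, a uniform
#' map to the frame centre). With `normalize = "softmax"` the map is passed
#' through an exponential first, which is the natural reading of log-domain
#' energy maps (equivalent to linear DSNT after leaving log space).
#'
#' @param h numeric matrix.
#' @param normalize "linear" or "softmax".
#' @return numeric (u, v), subpixel.
#' @export
softArgmax <- function(h, normalize = c("linear", "softmax")) {
  normalize <- match.arg(normalize)
  if (normalize == "linear") {
    w <- pmax(h, 0)
    s <- sum(w)
    if (s <= 0) stop("degenerate distribution: no positive mass after rectification")
    p <- w / s
  } else {
    z <- h - max(h)
    e <- exp(z)
    p <- e / sum(e)
  }
  g <- coordGrids(nrow(h), ncol(h))
  c(u = sum(p * g$u), v = sum(p * g$v))
}

#' Decode every channel of a heatmap stack
#'
#' @param stack a [HeatmapStack-class] or H x W x L array.
#' @param method "argmax" or "dsnt".
#' @return L x 2 matrix of (u, v) coordinates.
#' @export
decodeStack <- function(stack, method = c("argmax", "dsnt")) {
  method <- match.arg(method)
  grids <- if (is(stack, "HeatmapStack")) stack@grids else stack
  L <- dim(grids)[3]
  t(vapply(seq_len(L), function(i) {
    if (method == "argmax") decodeArgmax(grids[, , i]) else softArgmax(grids[, , i])
  }, numeric(2)))
}

# ---- serialization ----

#' Read/write heatmap stacks as multi-page 32-bit float TIFF
#'
#' @param stack a [HeatmapStack-class].
#' @param path file path.
#' @return `readHeatmapStack` returns a [HeatmapStack-class].
#' @export
writeHeatmapStack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF heatmap serialization")
  grids <- stack@grids
  pages <- lapply(seq_len(dim(grids)[3]), function(i) grids[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname writeHeatmapStack
#' @export
readHeatmapStack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF heatmap serialization")
  pages <- tiff::readTIFF(path, all = TRUE)
  HeatmapStack(array(unlist(pages), c(dim(pages[[1]]), length(pages))))
}

#' Export one heatmap as a min-max scaled PNG (visualization)
#'
#' @param h numeric matrix.
#' @param path output PNG path.
#' @export
writeHeatmapPNG <- function(h, path) {
  rng <- range(h)
  img <- if (diff(rng) > 0) (h - rng[1]) / diff(rng) else h * 0
  png::writePNG(img, path)
  invisible(path)
}
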