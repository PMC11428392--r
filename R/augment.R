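# On-the-fly spatial, intensity and occlusion-box augmentation.

#' Augmentation configuration
#'
#' Defaults follow the training protocol for 256 x 256 inputs: uniform
#' translation in [-10, 10] px, rotation in [-0.2, 0.2] rad about the frame
#' centre, elastic deformation from a 5 x 5 control grid whose points shift
#' uniformly by up to 20 px (interpolated with a cubic spline), intensity
#' shift and scale in [-0.15, 0.15] after normalization to [-1, 1], and one
#' occlusion box per batch covering 1-15% of the pixels.
#'
#' @param resizeTo target frame (H, W).
#' @param translatePx translation interval (px).
#' @param rotateRad rotation interval (radians).
#' @param elasticGrid control grid size per axis.
#' @param elasticAmpPx elastic control-point amplitude (px).
#' @param intensityShift additive shift interval (after [-1, 1] normalization).
#' @param intensityScale multiplicative scale interval v: new = old * (1 + v).
#' @param occlusionAreaFrac box area as a fraction of the frame.
#' @param occlusionAspect box aspect-ratio (width/height) interval.
#' @param occlusionEnabled logical.
#' @param perPixelShift if TRUE the intensity shift is resampled per pixel
#'   instead of once per image (default FALSE: one shift per image).
#' @return a validated config list.
#' @export
augmentConfig <- function(resizeTo = c(256L, 256L),
                          translatePx = c(-10, 10),
                          rotateRad = c(-0.2, 0.2),
                          elasticGrid = 5L,
                          elasticAmpPx = 20,
                          intensityShift = c(-0.15, 0.15),
                          intensityScale = c(-0.15, 0.15),
                          occlusionAreaFrac = c(0.01, 0.15),
                          occlusionAspect = c(0.5, 2),
                          occlusionEnabled = TRUE,
                          perPixelShift = FALSE) {
  stopifnot(translatePx[1] <= translatePx[2], rotateRad[1] <= rotateRad[2],
            occlusionAreaFrac[1] <= occlusionAreaFrac[2],
            all(occlusionAreaFrac > 0), all(occlusionAreaFrac < 1),
            elasticGrid >= 2, elasticAmpPx >= 0)
  list(resizeTo = as.integer(resizeTo), translatePx = translatePx,
       rotateRad = rotateRad, elasticGrid = as.integer(elasticGrid),
       elasticAmpPx = elasticAmpPx, intensityShift = intensityShift,
       intensityScale = intensityScale, occlusionAreaFrac = occlusionAreaFrac,
       occlusionAspect = occlusionAspect, occlusionEnabled = occlusionEnabled,
       perPixelShift = perPixelShift)
}

# Resize an image matrix to (H, W) with bicubic area-aligned resampling and
# map landmark coordinates accordingly.
resizeImageTo <- function(image, landmarks, frame) {
  H <- frame[1]; W <- frame[2]
  d <- dim(image)
  if (all(d == frame)) return(list(image = image, landmarks = landmarks))
  img <- matrix(resizeBicubic(array(image, c(d, 1, 1)), H, W), H, W)
  if (!is.null(landmarks)) {
    co <- landmarkCoords(landmarks)
    co[, 1] <- (co[, 1] + 0.5) * (W / d[2]) - 0.5
    co[, 2] <- (co[, 2] + 0.5) * (H / d[1]) - 0.5
    landmarks <- LandmarkSet(co, landmarkVisible(landmarks), imageId(landmarks))
  }
  list(image = img, landmarks = landmarks)
}

# Bilinear sampling of a matrix at (u, v) positions (0-based); 0 outside.
bilinearSample <- function(img, u, v) {
  H <- nrow(img); W <- ncol(img)
  u0 <- floor(u); v0 <- floor(v)
  fu <- u - u0; fv <- v - v0
  val <- function(vv, uu) {
    ok <- uu >= 0 & uu <= W - 1 & vv >= 0 & vv <= H - 1
    out <- numeric(length(uu))
    out[ok] <- img[cbind(vv[ok] + 1, uu[ok] + 1)]
    out
  }
  (1 - fu) * (1 - fv) * val(v0, u0) + fu * (1 - fv) * val(v0, u0 + 1) +
    (1 - fu) * fv * val(v0 + 1, u0) + fu * fv * val(v0 + 1, u0 + 1)
}

# Sample the spatial-transform parameters once.
sampleSpatialParams <- function(cfg) {
  g <- cfg$elasticGrid
  list(
    t = stats::runif(2, cfg$translatePx[1], cfg$translatePx[2]),
    theta = stats::runif(1, cfg$rotateRad[1], cfg$rotateRad[2]),
    du = matrix(stats::runif(g * g, -cfg$elasticAmpPx, cfg$elasticAmpPx), g, g),
    dv = matrix(stats::runif(g * g, -cfg$elasticAmpPx, cfg$elasticAmpPx), g, g))
}

#' Spatial augmentation of an image and its landmarks
#'
#' Applies one sampled translation + rotation + elastic deformation
#' identically to the image (backward warp with linear resampling) and to the
#' landmark coordinates (forward map obtained by numerically inverting the
#' warp, so a marker painted at a landmark lands on the transformed
#' landmark). Landmarks mapped outside the frame are flagged invisible so the
#' training loss can mask them.
#'
#' @param image numeric H x W matrix (or `NULL` to transform landmarks only).
#' @param landmarks a [LandmarkSet-class] in the same frame.
#' @param cfg an [augmentConfig()].
#' @param seed optional integer seed.
#' @param params optional pre-sampled transform parameters (internal reuse).
#' @return list(image, landmarks, params).
#' @export
spatialTransform <- function(image, landmarks, cfg = augmentConfig(),
                             seed = NULL, params = NULL) {
  withSeed(seed, {
    H <- cfg$resizeTo[1]; W <- cfg$resizeTo[2]
    if (!is.null(image) && !all(dim(image) == cfg$resizeTo)) {
      rs <- resizeImageTo(image, landmarks, cfg$resizeTo)
      image <- rs$image; landmarks <- rs$landmarks
    }
    if (is.null(params)) params <- sampleSpatialParams(cfg)
    ctr <- c((W - 1) / 2, (H - 1) / 2)
    # dense backward elastic field (cubic interpolation of the control grid)
    Eu <- matrix(resizeBicubic(params$du, H, W, convention = "corners"), H, W)
    Ev <- matrix(resizeBicubic(params$dv, H, W, convention = "corners"), H, W)
    cs <- cos(params$theta); sn <- sin(params$theta)
    # backward warp: output pixel x samples source position
    #   src(x) = R(-theta) (x - c - t) + c + E(x)
    if (!is.null(image)) {
      g <- coordGrids(H, W)
      xu <- g$u - ctr[1] - params$t[1]
      xv <- g$v - ctr[2] - params$t[2]
      su <- cs * xu + sn * xv + ctr[1] + Eu
      sv <- -sn * xu + cs * xv + ctr[2] + Ev
      image <- cpp_warp_bilinear(image, su, sv)
    }
    if (!is.null(landmarks)) {
      co <- landmarkCoords(landmarks)
      vis <- landmarkVisible(landmarks)
      # fixed-point inversion of the backward warp, all landmarks at once
      rotFwd <- function(m) cbind(cs * m[, 1] - sn * m[, 2],
                                  sn * m[, 1] + cs * m[, 2])
      base <- co; base[!vis, ] <- 0
      lp <- sweep(rotFwd(sweep(base, 2, ctr)), 2, ctr + params$t, `+`)
      for (k in 1:8) {
        cu <- pmin(pmax(lp[, 1], 0), W - 1)
        cv <- pmin(pmax(lp[, 2], 0), H - 1)
        e <- cbind(bilinearSample(Eu, cu, cv), bilinearSample(Ev, cu, cv))
        lp <- sweep(rotFwd(sweep(base - e, 2, ctr)), 2, ctr + params$t, `+`)
      }
      newco <- co
      newco[vis, ] <- lp[vis, ]
      inside <- vis & newco[, 1] >= 0 & newco[, 1] <= W - 1 &
        newco[, 2] >= 0 & newco[, 2] <= H - 1
      landmarks <- LandmarkSet(newco, inside, imageId(landmarks))
    }
    list(image = image, landmarks = landmarks, params = params)
  })
}

#' Intensity augmentation
#'
#' Normalizes the image to [-1, 1] (a constant image maps to all zeros), adds
#' one sampled shift to every pixel, then rescales every pixel by
#' `new = old * (1 + v)` with one sampled `v` per image.
#'
#' @param image numeric matrix.
#' @param cfg an [augmentConfig()].
#' @param seed optional integer seed.
#' @return transformed image matrix.
#' @export
intensityTransform <- function(image, cfg = augmentConfig(), seed = NULL) {
  withSeed(seed, {
    rng <- range(image)
    img <- if (diff(rng) > 0) 2 * (image - rng[1]) / diff(rng) - 1 else image * 0
    shift <- if (cfg$perPixelShift)
      matrix(stats::runif(length(img), cfg$intensityShift[1], cfg$intensityShift[2]),
             nrow(img), ncol(img))
    else stats::runif(1, cfg$intensityShift[1], cfg$intensityShift[2])
    v <- stats::runif(1, cfg$intensityScale[1], cfg$intensityScale[2])
    (img + shift) * (1 + v)
  })
}

#' Batch-wide occlusion box perturbation
#'
#' Samples one box (area fraction, aspect ratio and position) and fills it
#' with i.i.d. random intensities at the same location in every image of the
#' batch, fully removing local appearance there. Target landmarks are never
#' modified.
#'
#' @param batch numeric H x W x B array.
#' @param cfg an [augmentConfig()].
#' @param seed optional integer seed.
#' @return list(batch, box = c(u0, v0, w, h)) (0-based corner, px sizes);
#'   the input batch is returned untouched when occlusion is disabled.
#' @export
occlusionBoxes <- function(batch, cfg = augmentConfig(), seed = NULL) {
  if (!cfg$occlusionEnabled) return(list(batch = batch, box = NULL))
  withSeed(seed, {
    d <- dim(batch)
    H <- d[1]; W <- d[2]; B <- d[3]
    frac <- stats::runif(1, cfg$occlusionAreaFrac[1], cfg$occlusionAreaFrac[2])
    aspect <- stats::runif(1, cfg$occlusionAspect[1], cfg$occlusionAspect[2])
    area <- frac * H * W
    bw <- max(1L, min(W, as.integer(round(sqrt(area * aspect)))))
    bh <- max(1L, min(H, as.integer(round(sqrt(area / aspect)))))
    u0 <- sample.int(W - bw + 1L, 1L) - 1L
    v0 <- sample.int(H - bh + 1L, 1L) - 1L
    rows <- (v0 + 1):(v0 + bh); cols <- (u0 + 1):(u0 + bw)
    for (b in seq_len(B)) {
      rngb <- range(batch[, , b])
      batch[rows, cols, b] <- stats::runif(bh * bw, rngb[1], rngb[2])
    }
    list(batch = batch, box = c(u0 = u0, v0 = v0, w = bw, h = bh))
  })
}
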