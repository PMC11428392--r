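# Procedural generator of hand-like images with 37 consistent annotations.

#' Canonical 37-landmark hand template
#'
#' Hand-designed synthetic coordinate table on a 256 x 256 frame (not an
#' anatomical ground truth): a carpal block containing the wrist pair (2, 6)
#' at a nominal 50 px separation — so the physical scale works out to about
#' 1 mm per pixel — and five finger chains matching [fingerGrouping()].
#' Coordinates are rescaled when a different frame is requested.
#'
#' @param frame target frame (H, W), default c(256, 256).
#' @return 37 x 2 matrix of (u, v) coordinates.
#' @export
handTemplate <- function(frame = c(256L, 256L)) {
  path <- system.file("extdata", "hand_template_synthetic.csv", package = "gaffa")
  tab <- utils::read.csv(path)
  co <- as.matrix(tab[order(tab$index), c("u", "v")])
  if (!all(frame == c(256L, 256L))) {
    co[, 1] <- (co[, 1] + 0.5) * (frame[2] / 256) - 0.5
    co[, 2] <- (co[, 2] + 0.5) * (frame[1] / 256) - 0.5
  }
  rownames(co) <- NULL
  co
}

# Bone segments rendered as ridges: carpal chain, metacarpal attachments and
# finger chains (cross-finger rung edges of the refinement topology are
# constraints, not bones, and are not drawn).
handBones <- function() {
  chain <- function(v) cbind(v[-length(v)], v[-1])
  rbind(chain(1:13),
        cbind(9:13, c(18L, 17L, 16L, 15L, 14L)),
        chain(c(14, 22, 23, 24, 25)), chain(c(15, 26, 27, 28, 29)),
        chain(c(16, 30, 31, 32, 33)), chain(c(17, 34, 35, 36, 37)),
        chain(c(18, 19, 20, 21)))
}

#' Synthetic hand dataset configuration
#'
#' Global affine variation (rotation within 0.15 rad, scale 0.9-1.1,
#' translation within 10 px), per-landmark jitter of 1.5 px, bone ridges of
#' 4 px width and background noise of sd 0.05 emulate the pose and anatomy
#' variation of a hand radiograph collection at a level where displacement
#' priors are learnable and occlusion tests are meaningful.
#'
#' @param nImages number of images.
#' @param frame frame (H, W).
#' @param rotation max |rotation| in radians.
#' @param scaleRange global scale interval.
#' @param translatePx max |translation| per axis in px.
#' @param jitterSd per-landmark jitter standard deviation (px).
#' @param ridgeWidth bone ridge width (px).
#' @param jointSigma joint bump width (px).
#' @param noiseSd background noise standard deviation.
#' @param seed RNG seed.
#' @return a config list.
#' @export
syntheticConfig <- function(nImages = 60L, frame = c(256L, 256L),
                            rotation = 0.15, scaleRange = c(0.9, 1.1),
                            translatePx = 10, jitterSd = 1.5,
                            ridgeWidth = 4, jointSigma = 3,
                            noiseSd = 0.05, seed = 1L) {
  stopifnot(jitterSd >= 0, noiseSd >= 0, ridgeWidth > 0)
  list(nImages = as.integer(nImages), frame = as.integer(frame),
       rotation = rotation, scaleRange = scaleRange, translatePx = translatePx,
       jitterSd = jitterSd, ridgeWidth = ridgeWidth, jointSigma = jointSigma,
       noiseSd = noiseSd, seed = as.integer(seed))
}

# squared distance from every frame pixel to segment AB (0-based coords)
segmentDist2 <- function(g, A, B) {
  ab <- B - A
  len2 <- sum(ab^2)
  if (len2 == 0) return((g$u - A[1])^2 + (g$v - A[2])^2)
  t <- ((g$u - A[1]) * ab[1] + (g$v - A[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  (g$u - (A[1] + t * ab[1]))^2 + (g$v - (A[2] + t * ab[2]))^2
}

#' Sample one synthetic hand image with exact annotations
#'
#' Applies a global affine (rotation, scale, translation about the frame
#' centre) plus per-landmark jitter to the template, renders every bone as a
#' soft ridge and every joint as a Gaussian bump, and adds background noise.
#' The returned landmarks are the exact post-transform coordinates.
#'
#' @param cfg a [syntheticConfig()].
#' @param imageId identifier for the generated image.
#' @param seed optional integer seed.
#' @return list(image = H x W matrix in [0, 1], landmarks = [LandmarkSet-class]).
#' @export
sampleHand <- function(cfg = syntheticConfig(), imageId = "synth", seed = NULL) {
  withSeed(seed, {
    H <- cfg$frame[1]; W <- cfg$frame[2]
    tmpl <- handTemplate(cfg$frame)
    ctr <- c((W - 1) / 2, (H - 1) / 2)
    th <- stats::runif(1, -cfg$rotation, cfg$rotation)
    sc <- stats::runif(1, cfg$scaleRange[1], cfg$scaleRange[2])
    tr <- stats::runif(2, -cfg$translatePx, cfg$translatePx)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    co <- t(sc * R %*% t(sweep(tmpl, 2, ctr))) + rep(1, 37) %o% (ctr + tr)
    co <- co + matrix(stats::rnorm(74, 0, cfg$jitterSd), 37, 2)
    g <- coordGrids(H, W)
    img <- matrix(0, H, W)
    w2 <- 2 * cfg$ridgeWidth^2
    for (k in seq_len(nrow(handBones()))) {
      e <- handBones()[k, ]
      img <- pmax(img, 0.6 * exp(-segmentDist2(g, co[e[1], ], co[e[2], ]) / w2))
    }
    j2 <- 2 * cfg$jointSigma^2
    for (i in 1:37) {
      d2 <- (g$u - co[i, 1])^2 + (g$v - co[i, 2])^2
      img <- pmax(img, exp(-d2 / j2))
    }
    img <- img + matrix(stats::rnorm(H * W, 0, cfg$noiseSd), H, W)
    img <- pmin(pmax(img, 0), 1)
    vis <- co[, 1] >= 0 & co[, 1] <= W - 1 & co[, 2] >= 0 & co[, 2] <= H - 1
    list(image = img, landmarks = LandmarkSet(co, vis, imageId))
  })
}

#' Generate an in-memory synthetic hand dataset with three-fold splits
#'
#' @param cfg a [syntheticConfig()].
#' @return list with `images` (list of matrices), `landmarks` (list of
#'   [LandmarkSet-class]), `ids`, and `folds`: three train/test index splits
#'   partitioning the images (2/3 train, 1/3 test per fold).
#' @export
sampleHandDataset <- function(cfg = syntheticConfig()) {
  withSeed(cfg$seed, {
    n <- cfg$nImages
    ids <- sprintf("synth%04d", seq_len(n))
    samples <- lapply(seq_len(n), function(k)
      sampleHand(cfg, imageId = ids[k]))
    group <- rep(1:3, length.out = n)
    folds <- lapply(1:3, function(f)
      list(train = which(group != f), test = which(group == f)))
    list(images = lapply(samples, `[[`, "image"),
         landmarks = lapply(samples, `[[`, "landmarks"),
         ids = ids, folds = folds, frame = cfg$frame)
  })
}

#' Write a synthetic dataset to the standard directory layout
#'
#' Creates `images/` (PNG), `annotations/` (CSV rows index,u,v) and `splits/`
#' (plain-text id lists per fold). Byte-identical across runs with the same
#' config and seed (coordinates written with 4 decimals).
#'
#' @param cfg a [syntheticConfig()].
#' @param dir output directory.
#' @return (invisibly) the dataset manifest, see [datasetManifest()].
#' @export
makeHandDataset <- function(cfg = syntheticConfig(), dir) {
  ds <- sampleHandDataset(cfg)
  for (sub in c("images", "annotations", "splits"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(ds$ids)) {
    png::writePNG(ds$images[[k]], file.path(dir, "images", paste0(ds$ids[k], ".png")))
    writeAnnotations(ds$landmarks[[k]],
                     file.path(dir, "annotations", paste0(ds$ids[k], ".csv")))
  }
  for (f in 1:3) {
    writeLines(ds$ids[ds$folds[[f]]$train],
               file.path(dir, "splits", sprintf("fold%d_train.txt", f)))
    writeLines(ds$ids[ds$folds[[f]]$test],
               file.path(dir, "splits", sprintf("fold%d_test.txt", f)))
  }
  invisible(datasetManifest(dir))
}
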