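# External graphical-model refinement: blob candidates from the localization
# heatmaps, t-distribution / distance-ratio pairwise costs, and loopy belief
# propagation on the landmark graph. Unlike the differentiable refinement
# layer, this is a separate post-processing step.

# ---- Laplacian-of-Gaussian blob detection ----

# scale-normalized LoG response via FFT filtering (negated: bright blobs give
# positive response).
logResponse <- function(h, sigma) {
  H <- nrow(h); W <- ncol(h)
  r <- ceiling(4 * sigma)
  y <- (-r):r
  k <- outer(y^2, y^2, `+`)
  g <- exp(-k / (2 * sigma^2))
  g <- g / sum(g)
  lap <- g * (k / sigma^4 - 2 / sigma^2)     # Laplacian of the Gaussian
  kern <- sigma^2 * lap                       # scale normalization
  # same-size FFT convolution (zero padded, centre-aligned)
  P1 <- H + 2 * r; P2 <- W + 2 * r
  A <- matrix(0, P1, P2); A[1:H, 1:W] <- h
  B <- matrix(0, P1, P2); B[1:(2 * r + 1), 1:(2 * r + 1)] <- kern
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (P1 * P2)
  -full[(r + 1):(r + H), (r + 1):(r + W)]
}

localMaxima <- function(resp, threshold = 0) {
  H <- nrow(resp); W <- ncol(resp)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- resp
  isMax <- resp >= threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    isMax <- isMax & (resp >= pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)])
  }
  which(isMax, arr.ind = TRUE)
}

#' Extract blob candidates from a heatmap
#'
#' Multiscale Laplacian-of-Gaussian blob detection (scales matched to the
#' target blob width), ranking candidates by the heatmap intensity at the
#' blob peak. Only the strongest `maxN` candidates are kept; their peaks are
#' normalized to sum to one and candidates whose normalized peak falls below
#' `minNormPeak` are discarded.
#'
#' @param h numeric heatmap matrix.
#' @param maxN maximum number of candidates processed (default 25).
#' @param minNormPeak normalized-peak threshold (default 0.015).
#' @param sigmas LoG scales in px (default 2, 3, 4).
#' @return data.frame with columns u, v (0-based), peak, norm — possibly with
#'   zero rows when the heatmap has no blob-like structure (callers fall back
#'   to the raw argmax).
#' @export
extractCandidates <- function(h, maxN = 25L, minNormPeak = 0.015,
                              sigmas = c(2, 3, 4)) {
  if (any(!is.finite(h))) stop("heatmap must be finite")
  hits <- list()
  floorResp <- 1e-6 * max(abs(h), 1e-12)
  for (s in sigmas) {
    resp <- logResponse(h, s)
    mx <- localMaxima(resp, threshold = floorResp)
    if (nrow(mx)) hits[[length(hits) + 1]] <-
      data.frame(v = mx[, 1] - 1, u = mx[, 2] - 1, resp = resp[mx])
  }
  if (!length(hits)) return(data.frame(u = numeric(0), v = numeric(0),
                                       peak = numeric(0), norm = numeric(0)))
  cand <- do.call(rbind, hits)
  # merge across scales: keep the strongest response per pixel
  key <- paste(cand$u, cand$v)
  cand <- cand[order(-cand$resp), ]
  cand <- cand[!duplicated(paste(cand$u, cand$v)), ]
  cand$peak <- h[cbind(cand$v + 1, cand$u + 1)]
  cand <- cand[cand$peak > 0, , drop = FALSE]
  if (!nrow(cand)) return(data.frame(u = numeric(0), v = numeric(0),
                                     peak = numeric(0), norm = numeric(0)))
  cand <- cand[order(-cand$peak), , drop = FALSE]
  cand <- utils::head(cand, maxN)
  cand$norm <- cand$peak / sum(cand$peak)
  cand <- cand[cand$norm >= minNormPeak, , drop = FALSE]
  rownames(cand) <- NULL
  cand[, c("u", "v", "peak", "norm")]
}

# ---- t-distribution edge statistics ----

# negative log-likelihood of a location-scale t distribution
tNegLogLik <- function(par, x) {
  mu <- par[1]; sigma <- exp(par[2]); nu <- exp(par[3])
  -sum(stats::dt((x - mu) / sigma, df = nu, log = TRUE) - log(sigma))
}

#' Fit location-scale t-distributions to edge distances
#'
#' For every topology edge, fits a t-distribution (location, scale, degrees
#' of freedom by maximum likelihood) to the landmark pair distances observed
#' in the training annotations, and returns the three edges with the lowest
#' fitted scale as the fixed reference set used by the ratio costs.
#'
#' @param landmarks list of [LandmarkSet-class] training annotations.
#' @param topology a [Topology-class].
#' @param scales optional per-image mm-per-pixel constants; when supplied,
#'   distances are normalized to millimetres before fitting.
#' @param sigmaFloor lower bound on the fitted scale (default 1e-2).
#' @return list(edges = data.frame(a, b, mu, sigma, dof),
#'   referenceEdges = integer row indices of the three lowest-scale edges).
#' @export
fitEdgeStats <- function(landmarks, topology, scales = NULL, sigmaFloor = 1e-2) {
  if (length(landmarks) < 3) stop("need at least 3 training images")
  E <- topology@edges
  res <- data.frame(a = E[, 1], b = E[, 2], mu = NA_real_, sigma = NA_real_,
                    dof = NA_real_)
  for (k in seq_len(nrow(E))) {
    d <- vapply(seq_along(landmarks), function(m) {
      lm <- landmarks[[m]]
      if (!all(landmarkVisible(lm)[E[k, ]])) return(NA_real_)
      co <- landmarkCoords(lm)
      dd <- sqrt(sum((co[E[k, 1], ] - co[E[k, 2], ])^2))
      if (!is.null(scales)) dd * scales[[m]] else dd
    }, numeric(1))
    d <- d[is.finite(d)]
    mu0 <- stats::median(d); s0 <- max(stats::mad(d), sigmaFloor)
    fit <- tryCatch(
      suppressWarnings(
        stats::optim(c(mu0, log(s0), log(5)), tNegLogLik, x = d,
                     method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10))),
      error = function(e) NULL)
    if (is.null(fit)) {
      res$mu[k] <- mu0; res$sigma[k] <- s0; res$dof[k] <- 5
    } else {
      res$mu[k] <- fit$par[1]
      res$sigma[k] <- max(exp(fit$par[2]), sigmaFloor)
      res$dof[k] <- exp(fit$par[3])
    }
  }
  list(edges = res, referenceEdges = order(res$sigma)[seq_len(min(3, nrow(res)))])
}

#' @rdname fitEdgeStats
#' @param stats the object returned by `fitEdgeStats`.
#' @param path JSON path.
#' @export
writeEdgeStats <- function(stats, path) {
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fitEdgeStats
#' @export
readEdgeStats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$referenceEdges <- as.integer(x$referenceEdges)
  x
}

# log-density of a location-scale t
tLogDens <- function(x, mu, sigma, dof) {
  stats::dt((x - mu) / sigma, df = dof, log = TRUE) - log(sigma)
}

# ---- loopy belief propagation ----

# Sum-product LBP over a pairwise MRF given in log-potential form.
# unaries: list of numeric vectors (log phi_i); pairPot: list with $a, $b,
# $logpsi (|Da| x |Db| matrix). Synchronous schedule with damping; messages
# in log space, normalized by their log-sum-exp.
lbpSumProduct <- function(unaries, pairPot, maxIter = 100L, damping = 0.5,
                          tol = 1e-6) {
  nV <- length(unaries)
  # directed message store: key "a>b"
  msgs <- list()
  nbrs <- vector("list", nV)
  for (e in pairPot) {
    msgs[[paste0(e$a, ">", e$b)]] <- rep(0, length(unaries[[e$b]]))
    msgs[[paste0(e$b, ">", e$a)]] <- rep(0, length(unaries[[e$a]]))
    nbrs[[e$a]] <- c(nbrs[[e$a]], e$b)
    nbrs[[e$b]] <- c(nbrs[[e$b]], e$a)
  }
  edgeOf <- list()
  for (k in seq_along(pairPot)) {
    e <- pairPot[[k]]
    edgeOf[[paste(e$a, e$b)]] <- k
    edgeOf[[paste(e$b, e$a)]] <- k
  }
  logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    delta <- 0
    newMsgs <- msgs
    for (key in names(msgs)) {
      ab <- as.integer(strsplit(key, ">", fixed = TRUE)[[1]])
      a <- ab[1]; b <- ab[2]
      e <- pairPot[[edgeOf[[paste(a, b)]]]]
      lp <- if (e$a == a) e$logpsi else t(e$logpsi)   # |Da| x |Db|
      pre <- unaries[[a]]
      for (c in nbrs[[a]]) if (c != b) pre <- pre + msgs[[paste0(c, ">", a)]]
      m <- apply(lp + pre, 2, logsumexp)
      m <- m - logsumexp(m)
      m <- damping * msgs[[key]] + (1 - damping) * m
      delta <- max(delta, max(abs(m - msgs[[key]])))
      newMsgs[[key]] <- m
    }
    msgs <- newMsgs
    if (delta < tol) { converged <- TRUE; break }
  }
  beliefs <- lapply(seq_len(nV), function(a) {
    bl <- unaries[[a]]
    for (c in nbrs[[a]]) bl <- bl + msgs[[paste0(c, ">", a)]]
    bl - logsumexp(bl)
  })
  list(beliefs = beliefs, converged = converged)
}

# ratio cost of edge e with candidate distance d, against the reference edges
# (current top-candidate distances dRef, fitted locations muRef): the
# rescaled distance d * mu_f / d_f is scored under edge e's own fitted
# t-distribution and averaged over the references. Invariant to a global
# rescaling of all coordinates. This realization of the ratio comparison is a
# package convention; it is isolated here for easy revision.
ratioLogDens <- function(d, eStats, dRef, muRef) {
  ok <- dRef > 0
  if (!any(ok)) return(0)
  mean(tLogDens(d * muRef[ok] / dRef[ok], eStats$mu, eStats$sigma, eStats$dof))
}

#' Solve the candidate-assignment MRF with loopy belief propagation
#'
#' Builds a pairwise MRF whose variables are the landmarks (domains: their
#' blob candidates), with unary log-potentials `log(n_i)` from the normalized
#' blob peaks and pairwise log-potentials combining (a) the t-distribution
#' log-density of the candidate-pair distance and (b) ratio costs against the
#' three reference edges; the two families are rescaled to equal empirical
#' spread per image before being averaged. Sum-product messages run on a
#' synchronous schedule with damping until convergence, and each landmark
#' reports its max-marginal candidate.
#'
#' @param candidates list (length L) of candidate data.frames from
#'   [extractCandidates()]; every landmark needs at least one candidate.
#' @param edgeStats from [fitEdgeStats()].
#' @param topology a [Topology-class].
#' @param scale optional mm-per-pixel estimate used to normalize distances
#'   (when the edge statistics were fitted in millimetres).
#' @param maxIter,damping,tol LBP schedule controls.
#' @return list(coords = L x 2 matrix, picked = candidate indices,
#'   converged = logical).
#' @export
solveMrf <- function(candidates, edgeStats, topology, scale = NULL,
                     maxIter = 100L, damping = 0.5, tol = 1e-6) {
  L <- topology@nLandmarks
  stopifnot(length(candidates) == L)
  ncand <- vapply(candidates, nrow, integer(1))
  if (any(ncand == 0)) stop("every landmark needs at least one candidate")
  unaries <- lapply(candidates, function(cc) log(pmax(cc$norm, 1e-12)))
  E <- topology@edges
  est <- edgeStats$edges
  refs <- edgeStats$referenceEdges
  # current top-candidate distance of each reference edge
  topco <- t(vapply(candidates, function(cc) c(cc$u[1], cc$v[1]), numeric(2)))
  dRef <- vapply(refs, function(k)
    sqrt(sum((topco[est$a[k], ] - topco[est$b[k], ])^2)), numeric(1))
  if (!is.null(scale)) dRef <- dRef * scale
  muRef <- est$mu[refs]
  tTerms <- list(); rTerms <- list()
  for (k in seq_len(nrow(E))) {
    a <- E[k, 1]; b <- E[k, 2]
    ca <- candidates[[a]]; cb <- candidates[[b]]
    dmat <- sqrt(outer(ca$u, cb$u, `-`)^2 + outer(ca$v, cb$v, `-`)^2)
    if (!is.null(scale)) dmat <- dmat * scale
    tTerms[[k]] <- tLogDens(dmat, est$mu[k], est$sigma[k], est$dof[k])
    rTerms[[k]] <- apply(dmat, c(1, 2), ratioLogDens,
                         eStats = est[k, ], dRef = dRef, muRef = muRef)
  }
  # weight the two families to be equally important: rescale each to unit
  # empirical spread over all edges of this image
  spread <- function(lst) {
    v <- unlist(lst); s <- stats::sd(v[is.finite(v)]); if (!isTRUE(s > 0)) 1 else s
  }
  st <- spread(tTerms); sr <- spread(rTerms)
  pairPot <- lapply(seq_len(nrow(E)), function(k)
    list(a = E[k, 1], b = E[k, 2],
         logpsi = 0.5 * tTerms[[k]] / st + 0.5 * rTerms[[k]] / sr))
  sol <- lbpSumProduct(unaries, pairPot, maxIter = maxIter, damping = damping,
                       tol = tol)
  if (!sol$converged)
    warning("loopy belief propagation did not converge within ", maxIter,
            " iterations; returning current beliefs")
  picked <- vapply(sol$beliefs, which.max, integer(1))
  coords <- t(vapply(seq_len(L), function(i) {
    cc <- candidates[[i]][picked[i], ]
    c(cc$u, cc$v)
  }, numeric(2)))
  colnames(coords) <- c("u", "v")
  list(coords = coords, picked = picked, converged = sol$converged)
}

#' Graphical-model refinement of a heatmap stack
#'
#' Extracts blob candidates per landmark (falling back to the heatmap argmax
#' when none are found) and solves the assignment MRF.
#'
#' @param stack a [HeatmapStack-class] or H x W x L array.
#' @param edgeStats from [fitEdgeStats()].
#' @param topology a [Topology-class].
#' @param scale optional mm-per-pixel estimate (see [solveMrf()]).
#' @param maxN,minNormPeak candidate extraction controls.
#' @return L x 2 matrix of refined (u, v) coordinates.
#' @export
gmRefine <- function(stack, edgeStats, topology, scale = NULL,
                     maxN = 25L, minNormPeak = 0.015) {
  grids <- if (is(stack, "HeatmapStack")) stack@grids else stack
  L <- dim(grids)[3]
  candidates <- lapply(seq_len(L), function(i) {
    cc <- extractCandidates(grids[, , i], maxN = maxN, minNormPeak = minNormPeak)
    if (!nrow(cc)) {
      am <- decodeArgmax(grids[, , i])
      cc <- data.frame(u = am[1], v = am[2], peak = max(grids[, , i]), norm = 1)
    }
    cc
  })
  solveMrf(candidates, edgeStats, topology, scale = scale)$coords
}
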