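#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# Central S4 containers.
#
# Coordinate convention shared by every module: 0-based, (u, v) = (column,
# row), pixel centres at integer positions. A landmark at (u, v) sits at
# matrix element [v + 1, u + 1].
# ---------------------------------------------------------------------------

#' LandmarkSet: per-image 2-D landmark coordinates with visibility
#'
#' Holds the `L x 2` matrix of (u, v) pixel positions of one image's
#' landmarks (default `L = 37` for the hand configuration), a per-landmark
#' visibility flag (landmarks transformed out of the frame or absent from an
#' annotation file are marked invisible) and the image identifier.
#'
#' @slot coords numeric L x 2 matrix, columns `u`, `v`; rows may be `NA` only
#'   where the landmark is invisible.
#' @slot visible logical vector of length L.
#' @slot imageId single character identifier.
#' @export
setClass("LandmarkSet",
  representation(coords = "matrix", visible = "logical", imageId = "character"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@coords) != 2) msg <- c(msg, "coords must have two columns (u, v)")
    if (nrow(object@coords) != length(object@visible))
      msg <- c(msg, "visible must match the number of landmarks")
    bad <- object@visible & !stats::complete.cases(object@coords)
    if (any(bad)) msg <- c(msg, "visible landmarks must have finite coordinates")
    vis <- object@coords[object@visible, , drop = FALSE]
    if (length(vis) && !all(is.finite(vis)))
      msg <- c(msg, "visible landmark coordinates must be finite")
    if (length(object@imageId) != 1) msg <- c(msg, "imageId must be a single string")
    if (length(msg)) msg else TRUE
  })

#' Construct a LandmarkSet
#'
#' @param coords numeric L x 2 matrix of (u, v) pixel positions.
#' @param visible logical vector (default: rows with finite coordinates).
#' @param imageId image identifier string.
#' @return a [LandmarkSet-class] object.
#' @export
LandmarkSet <- function(coords, visible = NULL, imageId = "image") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("u", "v")
  if (is.null(visible)) visible <- stats::complete.cases(coords) & is.finite(rowSums(coords))
  new("LandmarkSet", coords = coords, visible = as.logical(visible),
      imageId = as.character(imageId))
}

#' @describeIn LandmarkSet number of landmarks
#' @param x a LandmarkSet
#' @export
setMethod("length", "LandmarkSet", function(x) nrow(x@coords))

#' Accessors for LandmarkSet
#' @param x a [LandmarkSet-class]
#' @return `landmarkCoords`: the L x 2 coordinate matrix; `landmarkVisible`:
#'   the logical visibility vector; `imageId`: the identifier.
#' @export
landmarkCoords <- function(x) x@coords

#' @rdname landmarkCoords
#' @export
landmarkVisible <- function(x) x@visible

#' @rdname landmarkCoords
#' @export
imageId <- function(x) x@imageId

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet '", object@imageId, "': ", nrow(object@coords),
      " landmarks (", sum(object@visible), " visible)\n", sep = "")
})

#' HeatmapStack: one real-valued grid per landmark in a shared frame
#'
#' @slot grids numeric H x W x L array.
#' @slot convention coordinate convention tag.
#' @export
setClass("HeatmapStack",
  representation(grids = "array", convention = "character"),
  validity = function(object) {
    if (length(dim(object@grids)) != 3) return("grids must be an H x W x L array")
    if (!all(is.finite(object@grids))) return("heatmap values must be finite")
    TRUE
  })

#' Construct a HeatmapStack
#' @param grids H x W x L array (or a list of equally sized matrices).
#' @return a [HeatmapStack-class].
#' @export
HeatmapStack <- function(grids) {
  if (is.list(grids)) grids <- array(unlist(grids), c(dim(grids[[1]]), length(grids)))
  if (length(dim(grids)) == 2) grids <- array(grids, c(dim(grids), 1))
  new("HeatmapStack", grids = grids, convention = "0-based (u,v)=(col,row)")
}

#' @rdname HeatmapStack
#' @param x a HeatmapStack
#' @param i landmark index
#' @return `heatmapChannel`: the H x W matrix of landmark `i`;
#'   `heatmapFrame`: the (H, W) frame.
#' @export
heatmapChannel <- function(x, i) x@grids[, , i]

#' @rdname HeatmapStack
#' @export
heatmapFrame <- function(x) dim(x@grids)[1:2]

setMethod("show", "HeatmapStack", function(object) {
  d <- dim(object@grids)
  cat("HeatmapStack: ", d[3], " channels of ", d[1], "x", d[2], "\n", sep = "")
})

#' Topology: undirected landmark graph with a fixed global-landmark set
#'
#' The graph encodes local anatomical neighborhoods (edges), while the global
#' set lists landmarks whose messages reach every other landmark during
#' refinement regardless of direct connection.
#'
#' @slot nLandmarks number of vertices.
#' @slot edges E x 2 integer matrix of unordered pairs (stored with i < j).
#' @slot globalSet integer vector of global landmark indices.
#' @export
setClass("Topology",
  representation(nLandmarks = "integer", edges = "matrix", globalSet = "integer"),
  validity = function(object) {
    msg <- character()
    e <- object@edges
    if (ncol(e) != 2) msg <- c(msg, "edges must have two columns")
    if (any(e < 1) || any(e > object@nLandmarks)) msg <- c(msg, "edge index out of range")
    if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-loops are not allowed")
    if (anyDuplicated(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
      msg <- c(msg, "duplicate edges")
    if (any(object@globalSet < 1) || any(object@globalSet > object@nLandmarks))
      msg <- c(msg, "global landmark index out of range")
    if (length(msg)) msg else TRUE
  })

#' Construct a Topology
#' @param nLandmarks number of landmarks (vertices).
#' @param edges two-column matrix of 1-based landmark index pairs.
#' @param globalSet indices of the global landmarks.
#' @return a [Topology-class].
#' @export
Topology <- function(nLandmarks, edges, globalSet = integer()) {
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2)
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
  new("Topology", nLandmarks = as.integer(nLandmarks), edges = edges,
      globalSet = sort(unique(as.integer(globalSet))))
}

#' @rdname Topology
#' @param x a Topology
#' @export
topologyEdges <- function(x) x@edges

#' @rdname Topology
#' @export
globalSet <- function(x) x@globalSet

#' @rdname Topology
#' @export
setMethod("length", "Topology", function(x) x@nLandmarks)

#' Local neighborhood of a landmark
#'
#' All landmarks connected to `i` by an edge.
#' @param topology a [Topology-class]
#' @param i landmark index
#' @return integer vector of neighbor indices (sorted).
#' @export
localNeighborhood <- function(topology, i) {
  e <- topology@edges
  sort(unique(c(e[e[, 1] == i, 2], e[e[, 2] == i, 1])))
}

#' Extended neighborhood of a landmark
#'
#' The union of the local neighborhood and the global landmark set, never
#' including `i` itself (a landmark does not message itself).
#' @inheritParams localNeighborhood
#' @return integer vector of neighbor indices (sorted).
#' @export
extendedNeighborhood <- function(topology, i) {
  setdiff(sort(unique(c(localNeighborhood(topology, i), topology@globalSet))), i)
}

setMethod("show", "Topology", function(object) {
  cat("Topology: ", object@nLandmarks, " landmarks, ", nrow(object@edges),
      " edges, |global set| = ", length(object@globalSet), "\n", sep = "")
})

#' ConditionalPrior: displacement heatmap p(i | j)
#'
#' Spatial density of landmark `i`'s position after landmark `j` has been
#' translated to the centre of a frame twice the size of the source images
#' (the doubling accommodates every displacement that fits the source frame).
#'
#' @slot pair ordered integer pair (i, j).
#' @slot grid non-negative density grid; full resolution is (2H) x (2W) for a
#'   source frame (H, W), optionally rasterized on a coarser pixel step.
#' @slot nComponents number of Gaussian mixture components selected.
#' @slot frame source frame (H, W).
#' @slot gridStep pixel spacing of the rasterized grid (1 = full resolution).
#' @export
setClass("ConditionalPrior",
  representation(pair = "integer", grid = "matrix", nComponents = "integer",
                 frame = "integer", gridStep = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@pair) != 2) msg <- c(msg, "pair must be (i, j)")
    if (any(object@grid < 0) || !all(is.finite(object@grid)))
      msg <- c(msg, "grid values must be finite and non-negative")
    expct <- 2L * object@frame %/% object@gridStep
    if (!all(dim(object@grid) == c(expct[1], expct[2])))
      msg <- c(msg, "grid must cover twice the source frame at the stated step")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "ConditionalPrior", function(object) {
  cat(sprintf("ConditionalPrior p(%d|%d): %dx%d grid (step %d), %d component(s)\n",
              object@pair[1], object@pair[2], nrow(object@grid), ncol(object@grid),
              object@gridStep, object@nComponents))
})

#' @rdname ConditionalPrior-class
#' @param x a ConditionalPrior
#' @export
priorGrid <- function(x) x@grid

#' PriorBank: conditional priors for every message edge of a topology
#'
#' @slot priors named list of [ConditionalPrior-class] keyed `"i|j"`.
#' @slot frame source frame (H, W).
#' @slot topology the [Topology-class] the bank covers.
#' @export
setClass("PriorBank",
  representation(priors = "list", frame = "integer", topology = "Topology"))

#' @rdname PriorBank-class
#' @param x a PriorBank
#' @param i,j landmark indices of the ordered pair (i | j)
#' @export
bankPrior <- function(x, i, j) {
  key <- paste0(i, "|", j)
  p <- x@priors[[key]]
  if (is.null(p)) stop("prior bank holds no entry for pair ", key)
  p
}

setMethod("show", "PriorBank", function(object) {
  cat("PriorBank: ", length(object@priors), " conditional priors on a ",
      object@frame[1], "x", object@frame[2], " frame\n", sep = "")
})

#' @rdname PriorBank-class
#' @export
setMethod("length", "PriorBank", function(x) length(x@priors))

#' MetricsSummary: point-error statistics with outlier counts
#'
#' @slot medianMm,meanMm,sdMm point-to-point error statistics in millimetres.
#' @slot outlierCounts named numeric: number of errors strictly exceeding each
#'   radius (names are the radii in mm).
#' @slot outlierPct same, as percentages of `nPredictions`.
#' @slot nPredictions number of predictions aggregated.
#' @export
setClass("MetricsSummary",
  representation(medianMm = "numeric", meanMm = "numeric", sdMm = "numeric",
                 outlierCounts = "numeric", outlierPct = "numeric",
                 nPredictions = "integer"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(-object@outlierCounts)) # non-increasing with radius
      msg <- c(msg, "outlier counts must be non-increasing as the radius grows")
    if (any(object@outlierPct < 0 | object@outlierPct > 100))
      msg <- c(msg, "percentages must lie in [0, 100]")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "MetricsSummary", function(object) {
  cat(sprintf("MetricsSummary over %d predictions\n", object@nPredictions))
  cat(sprintf("  PE (mm): median %.3f, mean %.3f, sd %.3f\n",
              object@medianMm, object@meanMm, object@sdMm))
  for (r in names(object@outlierCounts))
    cat(sprintf("  outliers > %s mm: %s (%.2f%%)\n", r,
                format(object@outlierCounts[[r]]), object@outlierPct[[r]]))
})
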