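# Dataset readers/writers, manifests and provenance records.

#' Read a landmark annotation file
#'
#' CSV with columns `index,u,v` (1-based landmark index, pixel coordinates,
#' subpixel precision preserved). Missing indices yield invisible landmarks;
#' duplicate indices are a parse error.
#'
#' @param path CSV path.
#' @param nLandmarks total number of landmarks (default 37).
#' @param imageId identifier (default: file name without extension).
#' @return a [LandmarkSet-class].
#' @export
readAnnotations <- function(path, nLandmarks = 37L, imageId = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.csv(path)
  if (!all(c("index", "u", "v") %in% names(tab)))
    stop("annotation file must have columns index,u,v: ", path)
  if (anyDuplicated(tab$index))
    stop("duplicate landmark index in ", path)
  if (any(tab$index < 1 | tab$index > nLandmarks))
    stop("landmark index out of range in ", path)
  co <- matrix(NA_real_, nLandmarks, 2)
  co[tab$index, 1] <- tab$u
  co[tab$index, 2] <- tab$v
  vis <- !is.na(co[, 1]) & !is.na(co[, 2])
  if (sum(vis) < nLandmarks)
    message(sprintf("%s: %d of %d landmarks annotated", path, sum(vis), nLandmarks))
  if (is.null(imageId)) imageId <- sub("\\.[^.]*$", "", basename(path))
  LandmarkSet(co, vis, imageId)
}

#' @rdname readAnnotations
#' @param landmarks a [LandmarkSet-class] to write; only visible landmarks are
#'   written, with 4-decimal coordinate precision.
#' @export
writeAnnotations <- function(landmarks, path) {
  vis <- which(landmarkVisible(landmarks))
  co <- landmarkCoords(landmarks)
  lines <- c("index,u,v",
             sprintf("%d,%.4f,%.4f", vis, co[vis, 1], co[vis, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a grayscale image (PNG or TIFF)
#'
#' Multichannel images are averaged to one grayscale channel.
#' @param path image path.
#' @return numeric H x W matrix.
#' @export
readImageGray <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF images")
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext, " (PNG and TIFF are supported)")
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  img
}

#' Dataset manifest for the standard directory layout
#'
#' Scans `images/`, `annotations/` and `splits/` under `dir`, checks that
#' every image has an annotation, and collects the split lists.
#'
#' @param dir dataset directory.
#' @param nLandmarks landmarks per image (default 37).
#' @return list(imagePaths, annotationPaths, ids, splits, nLandmarks).
#' @export
datasetManifest <- function(dir, nLandmarks = 37L) {
  imgs <- list.files(file.path(dir, "images"), full.names = TRUE)
  ids <- sub("\\.[^.]*$", "", basename(imgs))
  ann <- file.path(dir, "annotations", paste0(ids, ".csv"))
  missing <- !file.exists(ann)
  if (any(missing))
    stop("missing annotation file(s): ", paste(basename(ann[missing]), collapse = ", "))
  splitFiles <- list.files(file.path(dir, "splits"), full.names = TRUE)
  splits <- lapply(splitFiles, readLines)
  names(splits) <- sub("\\.txt$", "", basename(splitFiles))
  list(imagePaths = imgs, annotationPaths = ann, ids = ids,
       splits = splits, nLandmarks = as.integer(nLandmarks))
}

#' Write a JSON provenance record for a processing run
#'
#' @param path output JSON path.
#' @param config the configuration used (any list).
#' @param seed the seed used.
#' @param extra optional named list of further fields.
#' @export
writeProvenance <- function(path, config, seed, extra = list()) {
  rec <- c(list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("gaffa")),
    r_version = R.version.string,
    seed = seed,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    config = config), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Write predicted landmarks for a set of images as one CSV
#'
#' Columns: image_id, landmark, u, v.
#' @param predictions list of [LandmarkSet-class].
#' @param path CSV output path.
#' @export
writePredictionsCSV <- function(predictions, path) {
  rows <- lapply(predictions, function(p) {
    co <- landmarkCoords(p)
    data.frame(image_id = imageId(p), landmark = seq_len(nrow(co)),
               u = round(co[, 1], 4), v = round(co[, 2], 4))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
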