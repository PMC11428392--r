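# Physical-scale normalization and point-error statistics.

#' Millimetre-per-pixel normalization constant from the wrist pair
#'
#' Defines the physical scale of an image by declaring the wrist — the
#' segment between two designated wrist landmarks — to be 50 mm wide:
#' \eqn{s = 50 / \lVert l_a - l_b \rVert_2}.
#'
#' @param landmarks a [LandmarkSet-class].
#' @param wristA,wristB indices of the two wrist landmarks (defaults 2 and 6).
#' @param widthMm physical wrist width in millimetres (default 50).
#' @return scale in mm per pixel (strictly positive scalar).
#' @export
normalizationConstant <- function(landmarks, wristA = 2L, wristB = 6L, widthMm = 50) {
  co <- landmarkCoords(landmarks)
  vis <- landmarkVisible(landmarks)
  if (!vis[wristA] || !vis[wristB])
    stop("both wrist landmarks must be present to define the physical scale")
  d <- sqrt(sum((co[wristA, ] - co[wristB, ])^2))
  if (d <= 0) stop("degenerate scale: wrist landmarks coincide")
  widthMm / d
}

#' Point-to-point error in millimetres
#'
#' Euclidean prediction-target distance converted to millimetres with a
#' per-image scale constant.
#'
#' @param pred,target numeric (u, v) pixel positions, or n x 2 matrices.
#' @param scale mm-per-pixel constant (> 0).
#' @return error(s) in millimetres.
#' @export
pointError <- function(pred, target, scale) {
  if (!isScalarNumber(scale) || scale <= 0) stop("scale must be a positive number")
  pred <- rbind(pred); target <- rbind(target)
  e <- scale * sqrt(rowSums((pred - target)^2))
  if (length(e) == 1) as.numeric(e) else e
}

#' Summarize point errors with outlier statistics
#'
#' Median, mean and sample standard deviation of the supplied errors, plus the
#' number and percentage of errors strictly exceeding each radius. Every
#' supplied error is treated equally; masking of invisible landmarks is the
#' caller's responsibility.
#'
#' @param errorsMm non-negative numeric vector of point errors (mm).
#' @param radiiMm outlier radii in mm (default 2, 4, 10).
#' @return a [MetricsSummary-class].
#' @export
summarizeErrors <- function(errorsMm, radiiMm = c(2, 4, 10)) {
  if (length(errorsMm) == 0) stop("cannot summarize an empty error list")
  if (any(!is.finite(errorsMm)) || any(errorsMm < 0))
    stop("errors must be finite and non-negative")
  radiiMm <- sort(radiiMm)
  counts <- vapply(radiiMm, function(r) sum(errorsMm > r), numeric(1))
  names(counts) <- as.character(radiiMm)
  n <- length(errorsMm)
  new("MetricsSummary",
      medianMm = stats::median(errorsMm),
      meanMm = mean(errorsMm),
      sdMm = if (n > 1) stats::sd(errorsMm) else 0,
      outlierCounts = counts,
      outlierPct = 100 * counts / n,
      nPredictions = as.integer(n))
}

#' Outlier percentage for a count and denominator
#'
#' The count-to-percentage arithmetic used in summary tables:
#' \eqn{100 \cdot count / n}, reported to `digits` decimals.
#'
#' @param count outlier count.
#' @param n total number of predictions.
#' @param digits decimals for reporting (default 2).
#' @return percentage, rounded for reporting.
#' @export
outlierPercent <- function(count, n, digits = 2) {
  round(100 * count / n, digits)
}

#' Write a metrics report (CSV plus JSON twin)
#'
#' @param summary a [MetricsSummary-class].
#' @param csvPath,jsonPath output paths (either may be `NULL` to skip).
#' @return (invisibly) the metric table written.
#' @export
writeMetricsReport <- function(summary, csvPath = NULL, jsonPath = NULL) {
  stopifnot(is(summary, "MetricsSummary"))
  tab <- data.frame(
    metric = c("median_mm", "mean_mm", "sd_mm", "n_predictions",
               paste0("outliers_gt", names(summary@outlierCounts), "mm"),
               paste0("outlier_pct_gt", names(summary@outlierCounts), "mm")),
    value = c(summary@medianMm, summary@meanMm, summary@sdMm,
              summary@nPredictions, unname(summary@outlierCounts),
              round(unname(summary@outlierPct), 2)))
  if (!is.null(csvPath)) utils::write.csv(tab, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(stats::setNames(as.list(tab$value), tab$metric),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(tab)
}

#' Per-image, per-landmark error table
#'
#' @param predictions,targets lists of [LandmarkSet-class] (matched order).
#' @param scales per-image mm-per-pixel constants.
#' @param csvPath optional path for a CSV with columns image_id, landmark, pe_mm.
#' @return data.frame (image_id, landmark, pe_mm); invisible landmarks (in the
#'   target annotation) are omitted.
#' @export
perLandmarkErrorTable <- function(predictions, targets, scales, csvPath = NULL) {
  stopifnot(length(predictions) == length(targets),
            length(scales) == length(targets))
  rows <- lapply(seq_along(targets), function(k) {
    t <- targets[[k]]; p <- predictions[[k]]
    vis <- which(landmarkVisible(t))
    data.frame(image_id = imageId(t), landmark = vis,
               pe_mm = pointError(landmarkCoords(p)[vis, , drop = FALSE],
                                  landmarkCoords(t)[vis, , drop = FALSE],
                                  scales[[k]]))
  })
  out <- do.call(rbind, rows)
  if (!is.null(csvPath)) utils::write.csv(out, csvPath, row.names = FALSE)
  out
}
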