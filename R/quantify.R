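# The recruitment statistic: R = max POI intensity in ROI2 / mean POI
# intensity in ROI1, one value per cell, scored positive at R >= 2.

#' Compute the recruitment ratio R for one cell
#'
#' `R = max(POI over ROI2) / mean(POI over ROI1)`. The ROI1 mean includes
#' pixels that also belong to ROI2, and intensities are used raw (no
#' background subtraction, no smoothing before the maximum).
#'
#' @param poi_channel 2D intensity matrix (protein-of-interest channel).
#' @param roi1 A `cell_roi` (whole-cell ROI).
#' @param roi2 A `cluster_roi` (attachment-site ROI).
#' @param cell_id,condition,experiment Optional labels carried into the
#'   record.
#' @return A one-row data frame with columns `cell_id`, `condition`,
#'   `experiment`, `max_roi2`, `mean_roi1`, `R`. Positivity is assigned
#'   separately by [classify_positive()].
#' @section Errors: An empty ROI is a precondition error; a non-positive
#'   ROI1 mean makes the ratio undefined and raises an error.
#' @export
compute_ratio <- function(poi_channel, roi1, roi2,
                          cell_id = NA_character_,
                          condition = NA_character_,
                          experiment = NA_character_) {
  stopifnot(is.matrix(poi_channel))
  m1 <- if (inherits(roi1, "cell_roi")) roi1$mask else roi1
  m2 <- if (inherits(roi2, "cluster_roi")) roi2$mask else roi2
  if (!any(m1) || !any(m2)) {
    stop("empty ROI: both ROI1 and ROI2 must contain pixels", call. = FALSE)
  }
  mean_roi1 <- mean(poi_channel[m1])
  if (mean_roi1 <= 0) {
    stop("undefined ratio: ROI1 mean intensity is not positive",
         call. = FALSE)
  }
  max_roi2 <- max(poi_channel[m2])
  data.frame(
    cell_id = cell_id, condition = condition, experiment = experiment,
    max_roi2 = max_roi2, mean_roi1 = mean_roi1, R = max_roi2 / mean_roi1,
    stringsAsFactors = FALSE
  )
}

#' Classify a recruitment ratio as positive
#'
#' A cell is scored as showing recruitment when `R >= threshold`
#' (default 2, i.e. a two-fold local enrichment over the mean cellular
#' distribution). Set `strict = TRUE` for a strict `R > threshold` rule.
#'
#' @param R Recruitment ratio(s), must be positive.
#' @param threshold Positivity threshold (> 0).
#' @param strict Use `>` instead of `>=` at the boundary?
#' @return Logical vector.
#' @export
classify_positive <- function(R, threshold = 2, strict = FALSE) {
  if (!is.numeric(R) || any(!is.finite(R)) || any(R <= 0)) {
    stop("`R` must be positive and finite", call. = FALSE)
  }
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  if (strict) R > threshold else R >= threshold
}

#' Normalized intensity profile along a line
#'
#' Samples every channel by bilinear interpolation at `n_samples` equally
#' spaced points from `p0` to `p1` and scales each channel to its maximum
#' along the segment, so profiles are comparable across channels the way
#' published line scans are. A channel that is zero everywhere along the
#' segment is reported as all-zero rather than divided.
#'
#' @param field A `field_image`.
#' @param p0,p1 Segment endpoints as 0-based `(row, col)` coordinates,
#'   inside the field.
#' @param n_samples Number of samples (>= 2).
#' @return A data frame of class `line_scan_profile` with `position`
#'   (distance along the segment in pixels) and one normalized column per
#'   channel.
#' @export
line_scan <- function(field, p0, p1, n_samples = 100) {
  stopifnot(inherits(field, "field_image"), n_samples >= 2)
  shape <- dim(field$channels[[1]])
  pts <- rbind(p0, p1)
  if (any(pts < 0) || any(pts[, 1] > shape[1] - 1) ||
      any(pts[, 2] > shape[2] - 1)) {
    stop("line-scan endpoints must lie inside the field", call. = FALSE)
  }
  t <- seq(0, 1, length.out = n_samples)
  rp <- p0[1] + t * (p1[1] - p0[1])
  cp <- p0[2] + t * (p1[2] - p0[2])
  len <- sqrt(sum((p1 - p0)^2))
  out <- data.frame(position = t * len)
  for (nm in names(field$channels)) {
    z <- field$channels[[nm]]
    v <- pracma::interp2(x = 0:(shape[2] - 1), y = 0:(shape[1] - 1),
                         Z = z, xp = cp, yp = rp, method = "linear")
    m <- max(v)
    out[[nm]] <- if (m > 0) v / m else v
  }
  class(out) <- c("line_scan_profile", class(out))
  out
}

#' Quantify recruitment across a simulated or imported cohort
#'
#' Applies [segment_cell()], [segment_clusters()] and [compute_ratio()] to
#' every field. Cells whose segmentation fails (no cell, or no receptor
#' cluster -- e.g. no attached bacteria) are excluded from the records and
#' logged with the reason, mirroring the convention that only cells with
#' receptor-bound particles are scored.
#'
#' @param cohort List of entries as produced by [simulate_cohort()]; each
#'   entry needs `field`, and optionally `condition`, `experiment`,
#'   `cell_id`.
#' @param threshold,strict Positivity rule, see [classify_positive()].
#' @param min_area,cell_smooth_sigma Passed to [segment_cell()].
#' @param quantile,dilation_radius,cluster_smooth_sigma Passed to
#'   [segment_clusters()].
#' @return A list with `records` (one row per analysable cell, including a
#'   logical `positive` column) and `exclusions` (cell_id, condition,
#'   reason).
#' @export
quantify_cohort <- function(cohort, threshold = 2, strict = FALSE,
                            min_area = 500, cell_smooth_sigma = 2,
                            quantile = 0.995, dilation_radius = 3,
                            cluster_smooth_sigma = 1.5) {
  records <- list()
  exclusions <- list()
  for (entry in cohort) {
    cell_id <- entry$cell_id %||% NA_character_
    condition <- entry$condition %||% NA_character_
    experiment <- entry$experiment %||% NA_character_
    res <- tryCatch({
      roi1 <- segment_cell(entry$field$channels$poi, min_area = min_area,
                           smooth_sigma = cell_smooth_sigma)
      roi2 <- segment_clusters(entry$field$channels$receptor, roi1,
                               quantile = quantile,
                               dilation_radius = dilation_radius,
                               smooth_sigma = cluster_smooth_sigma)
      rec <- compute_ratio(entry$field$channels$poi, roi1, roi2,
                           cell_id = cell_id, condition = condition,
                           experiment = experiment)
      rec$positive <- classify_positive(rec$R, threshold, strict)
      rec
    }, error = function(e) e)
    if (inherits(res, "error")) {
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        cell_id = cell_id, condition = condition,
        reason = conditionMessage(res), stringsAsFactors = FALSE
      )
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  list(
    records = if (length(records)) do.call(rbind, records) else
      data.frame(cell_id = character(), condition = character(),
                 experiment = character(), max_roi2 = numeric(),
                 mean_roi1 = numeric(), R = numeric(), positive = logical(),
                 stringsAsFactors = FALSE),
    exclusions = if (length(exclusions)) do.call(rbind, exclusions) else
      data.frame(cell_id = character(), condition = character(),
                 reason = character(), stringsAsFactors = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
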