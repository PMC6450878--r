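# Automated stand-ins for the hand-drawn ROIs: ROI1 is the cell outline
# taken from the POI channel, ROI2 the clustered-receptor site taken from
# the receptor channel.

#' Segment the cell outline (ROI1) from the POI channel
#'
#' Gaussian smoothing, Otsu threshold, hole filling, then the largest
#' connected component. The Otsu threshold is computed on the min-max
#' normalized image, which makes the segmentation exactly invariant under
#' multiplicative intensity scaling.
#'
#' @param poi_channel 2D intensity matrix.
#' @param min_area Minimum accepted component area in pixels.
#' @param smooth_sigma Gaussian smoothing sigma in pixels (0 disables).
#' @return An object of class `cell_roi`: list with logical `mask` and
#'   numeric `area`.
#' @section Errors: A constant image, or a field in which no component
#'   reaches `min_area`, raises a `no-cell` error.
#' @export
segment_cell <- function(poi_channel, min_area = 500, smooth_sigma = 2) {
  stopifnot(is.matrix(poi_channel))
  rng <- range(poi_channel)
  if (diff(rng) == 0) {
    stop("no cell found: POI channel is constant", call. = FALSE)
  }
  sm <- poi_channel
  if (smooth_sigma > 0) {
    sm <- as.matrix(EBImage::gblur(sm, sigma = smooth_sigma))
  }
  rng <- range(sm)
  norm <- (sm - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > th
  mask <- as.matrix(EBImage::fillHull(mask)) > 0
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  if (length(areas) == 0 || max(areas) < min_area) {
    stop("no cell found: no connected component of at least ", min_area,
         " pixels", call. = FALSE)
  }
  keep <- which.max(areas)
  structure(list(mask = as.matrix(lab) == keep, area = max(areas)),
            class = "cell_roi")
}

#' Segment attachment-site clusters (ROI2) from the receptor channel
#'
#' Pixels strictly above a high intensity quantile of the (lightly
#' smoothed) receptor channel are dilated by `dilation_radius` and split
#' into connected components; components that do not touch the dilated
#' cell mask are discarded as off-cell debris, and the survivors are
#' unioned into a single ROI2 per cell. The quantile rule is used instead
#' of Otsu because cluster pixels are a tiny area fraction, where Otsu is
#' unstable.
#'
#' @param receptor_channel 2D intensity matrix.
#' @param cell A `cell_roi` from [segment_cell()].
#' @param quantile Intensity quantile defining cluster pixels.
#' @param dilation_radius Dilation radius in pixels (the micron scale of a
#'   bacterium).
#' @param smooth_sigma Pre-threshold smoothing sigma; suppresses
#'   shot-noise singletons so a contiguous site stays one component.
#' @return An object of class `cluster_roi`: logical `mask` (union of all
#'   surviving components) and `n_components`.
#' @section Errors: If no pixel exceeds the quantile (e.g. a uniform
#'   receptor channel) or no component touches the cell, a `no-cluster`
#'   error is raised; callers treat this as "cell excluded from analysis".
#' @export
segment_clusters <- function(receptor_channel, cell, quantile = 0.995,
                             dilation_radius = 3, smooth_sigma = 1.5) {
  stopifnot(is.matrix(receptor_channel), inherits(cell, "cell_roi"))
  sm <- receptor_channel
  if (smooth_sigma > 0) {
    sm <- as.matrix(EBImage::gblur(sm, sigma = smooth_sigma))
  }
  q <- stats::quantile(sm, quantile, names = FALSE)
  mask <- sm > q
  if (!any(mask)) {
    stop("no cluster found: no receptor pixel above the ",
         quantile, " quantile", call. = FALSE)
  }
  brush <- EBImage::makeBrush(2 * dilation_radius + 1, shape = "disc")
  mask <- as.matrix(EBImage::dilate(mask, brush)) > 0
  lab <- as.matrix(EBImage::bwlabel(mask))
  cell_dil <- as.matrix(EBImage::dilate(cell$mask, brush)) > 0
  touching <- sort(unique(lab[lab > 0 & cell_dil]))
  if (length(touching) == 0) {
    stop("no cluster found: no component touches the cell", call. = FALSE)
  }
  structure(list(mask = matrix(lab %in% touching, nrow(lab)),
                 n_components = length(touching)),
            class = "cluster_roi")
}

#' Intersection-over-union of two masks
#'
#' @param a,b Logical matrices of equal shape.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  sum(a & b) / sum(a | b)
}
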