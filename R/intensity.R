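# Intensity-based quantifications: gelatin degradation and channel ratios.

as_plane <- function(image, channel = 1, t = 1, z = 1) {
  if (inherits(image, "image_series")) get_plane(image, channel, t, z)
  else as.matrix(image)
}

#' Gelatin degradation metrics
#'
#' Degradation index of a labeled-gelatin field: the mean gelatin intensity
#' under the cell footprint normalized to the mean intensity in non-degraded
#' reference regions, plus the fraction of footprint pixels classified as
#' degraded by a threshold relative to the reference mean.
#'
#' @param gelatin an [image_series()] (gelatin channel) or matrix.
#' @param cell_mask,reference_mask logical (Y, X) matrices; must be
#'   non-empty and disjoint.
#' @param threshold_fraction a footprint pixel is degraded when its
#'   intensity falls below `threshold_fraction` x reference mean.
#' @param channel channel to use when `gelatin` is an image series.
#' @return `list(mean_ratio, degraded_area_fraction, threshold_used)`.
#' @export
degradation_metrics <- function(gelatin, cell_mask, reference_mask,
                                threshold_fraction = 0.5, channel = 1) {
  m <- as_plane(gelatin, channel)
  cell_mask <- as.logical(cell_mask)
  reference_mask <- as.logical(reference_mask)
  if (!any(cell_mask)) stop("cell_mask is empty")
  if (!any(reference_mask)) stop("reference_mask is empty")
  if (any(cell_mask & reference_mask)) stop("masks must be disjoint")
  ref_mean <- mean(m[reference_mask])
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    stop("reference region has non-positive mean intensity")
  }
  thr <- threshold_fraction * ref_mean
  list(
    mean_ratio = mean(m[cell_mask]) / ref_mean,
    degraded_area_fraction = mean(m[cell_mask] < thr),
    threshold_used = thr
  )
}

#' Background-subtracted mean intensity ratio of two channels
#'
#' Per-channel background (the median intensity outside the mask) is
#' subtracted before taking the ratio of in-mask means, so a constant
#' offset common to both channels cancels.
#'
#' @param img an [image_series()] with both channels.
#' @param channel_a,channel_b channel names or indices (numerator,
#'   denominator).
#' @param mask logical (Y, X) matrix of the region to quantify.
#' @param t,z frame / plane selectors.
#' @return Unitless ratio.
#' @export
intensity_ratio <- function(img, channel_a, channel_b, mask, t = 1, z = 1) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("mask is empty")
  a <- get_plane(img, channel_a, t, z)
  b <- get_plane(img, channel_b, t, z)
  bg_a <- if (all(mask)) 0 else median(a[!mask])
  bg_b <- if (all(mask)) 0 else median(b[!mask])
  num <- mean(a[mask]) - bg_a
  den <- mean(b[mask]) - bg_b
  if (!is.finite(den) || den <= 0) {
    stop("denominator channel has non-positive background-subtracted mean")
  }
  num / den
}
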