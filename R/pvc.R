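# Pair vector correlation: the mean dot product of velocity-vector pairs
# as a function of their spatial separation and temporal lag.

#' Pair vector correlation surface
#'
#' Over all pairs of distinct retained vectors, accumulates dot products
#' `v_i . v_j` into (delta-r bin, delta-t lag) cells and divides by the
#' pair count `M_pairs` of each cell:
#' `PVC(dr, dt) = (1 / M_pairs) * sum_i sum_j v_i . v_j`.
#' Spatial separation is Euclidean distance between ROI centers (um);
#' temporal lag is the absolute TOI index difference (+dt and -dt pairs are
#' pooled, which is symmetric because the dot product commutes). Cells with
#' no pairs are undefined (`NA`), never zero-filled. Aligned vectors give
#' positive contributions, anti-aligned ones negative; uncorrelated fields
#' average to zero.
#'
#' @param field a `vector_field` (or any data.frame with `x_um`, `y_um`,
#'   `toi`, `vx`, `vy`, `retained`).
#' @param dr_bin_width spatial bin width, um (default: the ROI grid spacing
#'   0.16 um when a config is attached, else 0.16).
#' @param max_dr largest separation binned, um.
#' @param max_dt largest TOI lag.
#' @param normalize use unit-normalized vectors so values lie in [-1, 1].
#' @return A `pvc_result`: `dr_bin_edges`, `dr_bin_centers` (um),
#'   `dt_lags`, `pvc_values` (bins x lags), `m_pairs`, `toi_step_min`.
#' @export
pair_vector_correlation <- function(field, dr_bin_width = NULL, max_dr = NULL,
                                    max_dt = NULL, normalize = FALSE) {
  cfg <- attr(field, "config")
  if (is.null(dr_bin_width)) {
    dr_bin_width <- if (!is.null(cfg)) cfg$roi_shift * cfg$pixel_size else 0.16
  }
  stopifnot(dr_bin_width > 0)
  v <- field[field$retained, , drop = FALSE]
  if (nrow(v) < 2) stop("need at least two retained vectors")
  if (is.null(max_dr)) {
    max_dr <- max(dist(cbind(v$x_um, v$y_um)))
  }
  if (is.null(max_dt)) max_dt <- max(v$toi) - min(v$toi)
  max_dt <- max(max_dt, 0)
  vec <- cbind(v$vx, v$vy)
  if (normalize) {
    nrm <- sqrt(rowSums(vec^2))
    nz <- nrm > 0
    vec[nz, ] <- vec[nz, ] / nrm[nz]
  }
  n <- nrow(v)
  dr <- as.matrix(dist(cbind(v$x_um, v$y_um)))
  dt <- abs(outer(v$toi, v$toi, "-"))
  dots <- tcrossprod(vec)
  ut <- upper.tri(dr)
  dr_p <- dr[ut]; dt_p <- dt[ut]; dot_p <- dots[ut]
  keep <- dr_p <= max_dr & dt_p <= max_dt
  dr_p <- dr_p[keep]; dt_p <- dt_p[keep]; dot_p <- dot_p[keep]
  n_bins <- ceiling(max_dr / dr_bin_width)
  n_bins <- max(n_bins, 1)
  bin <- pmin(floor(dr_p / dr_bin_width), n_bins - 1) + 1
  lag <- dt_p + 1
  cell <- (lag - 1) * n_bins + bin
  n_cells <- n_bins * (max_dt + 1)
  sums <- rep(0, n_cells)
  counts <- rep(0L, n_cells)
  agg_s <- tapply(dot_p, cell, sum)
  agg_n <- tapply(dot_p, cell, length)
  ids <- as.integer(names(agg_s))
  sums[ids] <- agg_s
  counts[ids] <- agg_n
  pvc <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(list(
    dr_bin_edges = seq(0, n_bins * dr_bin_width, by = dr_bin_width),
    dr_bin_centers = (seq_len(n_bins) - 0.5) * dr_bin_width,
    dt_lags = 0:max_dt,
    pvc_values = matrix(pvc, n_bins, max_dt + 1),
    m_pairs = matrix(counts, n_bins, max_dt + 1),
    normalized = isTRUE(normalize),
    toi_step_min = if (!is.null(cfg)) cfg$toi_shift * cfg$frame_interval / 60
                   else NA_real_
  ), class = "pvc_result")
}

#' Spatial and temporal extent of flow correlation
#'
#' Operationalizes "correlated up to X um / Y min": starting from the first
#' adequately sampled separation bin at zero temporal lag, the spatial
#' extent is the center of the last bin in the contiguous run whose PVC
#' stays at or above `threshold_fraction` of the reference (first-bin)
#' PVC — i.e. the separation at which the correlation first decays through
#' the threshold. The temporal extent is the analogous run along the
#' temporal-lag axis at the first spatial bin, converted to minutes when
#' the TOI step is known. Bins with fewer than `min_pairs` vector pairs are
#' treated as undefined (single sparse far-field cells would otherwise
#' dominate the estimate).
#'
#' @param result a [pair_vector_correlation()] result.
#' @param threshold_fraction fraction of the reference PVC.
#' @param min_pairs minimum `M_pairs` for a cell to enter the scan.
#' @return `list(spatial_extent_um, temporal_extent, temporal_extent_min)`.
#' @export
correlation_extent <- function(result, threshold_fraction = 0.5,
                               min_pairs = 5) {
  stopifnot(inherits(result, "pvc_result"))
  col0 <- result$pvc_values[, 1]
  col0[result$m_pairs[, 1] < min_pairs] <- NA
  if (all(is.na(col0))) stop("PVC undefined at zero temporal lag")
  i0 <- which(!is.na(col0))[1]
  ref <- col0[i0]
  if (!is.finite(ref) || ref <= 0) {
    stop("reference PVC (first defined bin at zero lag) is not positive")
  }
  run_end <- function(vals, axis, start) {
    last <- start
    for (k in seq(start, length(vals))) {
      if (is.na(vals[k])) next  # skip unsampled cells inside the run
      if (vals[k] >= threshold_fraction * ref) last <- k else break
    }
    axis[last]
  }
  spatial <- run_end(col0, result$dr_bin_centers, i0)
  row1 <- result$pvc_values[i0, ]
  row1[result$m_pairs[i0, ] < min_pairs] <- NA
  temporal <- run_end(row1, result$dt_lags, 1)
  list(spatial_extent_um = spatial,
       temporal_extent = temporal,
       temporal_extent_min = temporal * result$toi_step_min)
}

#' Average PVC surfaces across movies
#'
#' Arithmetic mean of per-movie PVC surfaces on a common grid (cells
#' undefined in a movie are ignored for that cell).
#'
#' @param results list of [pair_vector_correlation()] results with equal
#'   binning.
#' @return A `pvc_result` with pooled `m_pairs`.
#' @export
average_pvc <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "pvc_result")))
  nb <- vapply(results, function(r) length(r$dr_bin_centers), integer(1))
  nl <- vapply(results, function(r) length(r$dt_lags), integer(1))
  nbin <- min(nb); nlag <- min(nl)
  acc <- array(NA_real_, c(nbin, nlag, length(results)))
  mp <- matrix(0L, nbin, nlag)
  for (k in seq_along(results)) {
    acc[, , k] <- results[[k]]$pvc_values[seq_len(nbin), seq_len(nlag)]
    mp <- mp + results[[k]]$m_pairs[seq_len(nbin), seq_len(nlag)]
  }
  out <- results[[1]]
  out$dr_bin_centers <- out$dr_bin_centers[seq_len(nbin)]
  out$dr_bin_edges <- out$dr_bin_edges[seq_len(nbin + 1)]
  out$dt_lags <- out$dt_lags[seq_len(nlag)]
  out$pvc_values <- apply(acc, c(1, 2), mean, na.rm = TRUE)
  out$pvc_values[is.nan(out$pvc_values)] <- NA_real_
  out$m_pairs <- mp
  out
}
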