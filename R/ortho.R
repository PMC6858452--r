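# Orthogonal (radial x z) views of z-stacks and z-peak height extraction.

#' Orthogonal view around podosome centers
#'
#' For every z-plane the rotating-line sampler of [radial_profile()] is
#' applied around each center and averaged over angles, producing a
#' (radial x z) mean-intensity map; multiple centers are averaged, which is
#' the per-cluster pooling used when individual structures are too dim for
#' a reliable per-podosome peak fit. The z axis is reported relative to the
#' ventral reference plane: the z-plane of maximum total intensity in
#' `ventral_channel` (set `ventral_channel = NULL` to use the first plane).
#'
#' @param stack a calibrated z-stack [image_series()] (`z_step` set,
#'   more than one plane).
#' @param centers a `podosome_centers` object, matrix of (x, y) um, or a
#'   single `c(x, y)`.
#' @param channel channel to map.
#' @param half_length half line length, um.
#' @param n_angles number of line orientations.
#' @param ventral_channel channel defining the z reference plane.
#' @param t frame selector.
#' @return An `ortho_map`: `radial_axis` (um, two-sided), `z_axis` (um,
#'   zero at the ventral reference), `mean_intensity` (radial x z),
#'   `n_podosomes`.
#' @export
orthogonal_view <- function(stack, centers, channel = 1, half_length = 1.5,
                            n_angles = 90, ventral_channel = NULL, t = 1) {
  stopifnot(inherits(stack, "image_series"))
  nz <- n_planes(stack)
  if (nz < 2) stop("orthogonal views need a multi-plane z-stack")
  if (is.na(stack$z_step) || stack$z_step <= 0) {
    stop("stack has no z calibration (z_step)")
  }
  pts <- if (is.numeric(centers) && is.null(dim(centers)) &&
             length(centers) == 2) {
    matrix(centers, 1, 2)
  } else {
    center_coords(centers)
  }
  z_ref <- 1L
  if (!is.null(ventral_channel)) {
    totals <- vapply(seq_len(nz), function(iz) {
      sum(get_plane(stack, ventral_channel, t, iz))
    }, numeric(1))
    z_ref <- which.max(totals)
  }
  px <- stack$pixel_size
  k <- round(half_length / px)
  d_px <- -k:k
  angles <- (seq_len(n_angles) - 1) * pi / n_angles
  cosd <- outer(d_px, cos(angles))
  sind <- outer(d_px, sin(angles))
  radial_axis <- d_px * px
  acc <- matrix(0, length(d_px), nz)
  for (iz in seq_len(nz)) {
    m <- get_plane(stack, channel, t, iz)
    for (i in seq_len(nrow(pts))) {
      cx <- pts[i, 1] / px
      cy <- pts[i, 2] / px
      if (cx < 0 || cx > ncol(m) - 1 || cy < 0 || cy > nrow(m) - 1) {
        stop("center lies outside the image")
      }
      sm <- matrix(bilinear_sample(m, as.vector(cx + cosd),
                                   as.vector(cy + sind)),
                   length(d_px), n_angles)
      acc[, iz] <- acc[, iz] + rowMeans(sm, na.rm = TRUE)
    }
  }
  acc <- acc / nrow(pts)
  structure(list(
    radial_axis = radial_axis,
    z_axis = (seq_len(nz) - z_ref) * stack$z_step,
    mean_intensity = acc,
    n_podosomes = nrow(pts)
  ), class = "ortho_map")
}

#' Peak z-height at a radial distance
#'
#' Extracts the z-column of an orthogonal view at the requested radial
#' distance (nearest grid point, averaging the +r and -r columns), fits a
#' Gaussian with offset over z, and returns the fitted peak position and
#' amplitude. Flat columns return a no-peak flag instead of a fit.
#'
#' @param ortho an [orthogonal_view()] result.
#' @param radial_distance distance from the core center, um (e.g. 0 for the
#'   core, 0.45 for vinculin, 0.8 for myosin IIA / network actin).
#' @return `list(z_peak, peak_intensity, r_squared, has_peak)` (um).
#' @export
z_peak_height <- function(ortho, radial_distance) {
  stopifnot(inherits(ortho, "ortho_map"))
  if (radial_distance < 0 || radial_distance > max(abs(ortho$radial_axis))) {
    stop("radial_distance outside the mapped radial axis")
  }
  ip <- which.min(abs(ortho$radial_axis - radial_distance))
  im <- which.min(abs(ortho$radial_axis + radial_distance))
  col <- colMeans(ortho$mean_intensity[unique(c(ip, im)), , drop = FALSE])
  z <- ortho$z_axis
  if (sd(col) < .Machine$double.eps^0.5 * max(abs(col), 1)) {
    return(list(z_peak = NA_real_, peak_intensity = NA_real_,
                r_squared = NA_real_, has_peak = FALSE))
  }
  amp0 <- max(col) - min(col)
  z0 <- z[which.max(col)]
  fit <- tryCatch(
    nlsLM(col ~ A * exp(-(z - z0f)^2 / (2 * sz^2)) + c,
          start = list(A = amp0, z0f = z0, sz = diff(range(z)) / 6,
                       c = min(col)),
          lower = c(A = 0, z0f = min(z) - diff(range(z)),
                    sz = 1e-4, c = -Inf),
          upper = c(A = Inf, z0f = max(z) + diff(range(z)),
                    sz = diff(range(z)), c = Inf),
          control = nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # fall back to the discrete argmax
    return(list(z_peak = z0, peak_intensity = amp0, r_squared = NA_real_,
                has_peak = TRUE))
  }
  cf <- coef(fit)
  sst <- sum((col - mean(col))^2)
  list(z_peak = unname(cf[["z0f"]]),
       peak_intensity = unname(cf[["A"]]),
       r_squared = 1 - sum(resid(fit)^2) / sst,
       has_peak = TRUE)
}
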