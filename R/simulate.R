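# Synthetic podosome scene generation with known ground truth.
#
# Scenes are rendered noiselessly in photons, blurred by a normalized
# residual PSF, and then degraded by Poisson shot noise followed by additive
# Gaussian read noise (the standard fluorescence camera model). All
# randomness flows from the explicit integer seeds in the specs, so
# identical spec + seed is bit-identical.

# Hard-core placement by bounded rejection sampling.
place_hardcore <- function(n, field, min_sep, margin,
                           max_attempts = max(2000L, 2000L * n)) {
  if (n == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  if (2 * margin >= min(field)) stop("margin leaves no placeable area")
  pts <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    if (attempts >= max_attempts) {
      stop(sprintf(paste0(
        "failed to place %d centers at min_separation %.3g um in a ",
        "%.3g x %.3g um field after %d attempts (placed %d); ",
        "achievable density at this separation is about %.2f / um^2"),
        n, min_sep, field[1], field[2], attempts, placed,
        0.6 / min_sep^2))
    }
    attempts <- attempts + 1L
    p <- c(runif(1, margin, field[1] - margin),
           runif(1, margin, field[2] - margin))
    if (placed == 0L ||
        min((pts[seq_len(placed), 1] - p[1])^2 +
            (pts[seq_len(placed), 2] - p[2])^2) >= min_sep^2) {
      placed <- placed + 1L
      pts[placed, ] <- p
    }
  }
  pts
}

# Render a sum of Gaussian spots (ring_radius = 0) or Gaussian annuli
# (ring_radius > 0) into a (ny, nx) image. centers in um, per-spot
# amplitudes in photons. Only a local window around each spot is computed.
render_spots <- function(ny, nx, px, centers, amplitudes, sigma,
                         ring_radius = 0) {
  img <- matrix(0, ny, nx)
  if (nrow(centers) == 0) return(img)
  amplitudes <- rep_len(amplitudes, nrow(centers))
  rad_px <- ceiling((ring_radius + 5 * sigma) / px)
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1] / px
    cy <- centers[i, 2] / px
    xs <- max(0, floor(cx - rad_px)):min(nx - 1, ceiling(cx + rad_px))
    ys <- max(0, floor(cy - rad_px)):min(ny - 1, ceiling(cy + rad_px))
    if (length(xs) == 0 || length(ys) == 0) next
    r <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+")) * px
    v <- if (ring_radius > 0) {
      exp(-(r - ring_radius)^2 / (2 * sigma^2))
    } else {
      exp(-r^2 / (2 * sigma^2))
    }
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amplitudes[i] * v
  }
  img
}

add_camera_noise <- function(mat, read_noise_sigma) {
  n <- length(mat)
  noisy <- rpois(n, lambda = pmax(mat, 0))
  if (read_noise_sigma > 0) noisy <- noisy + rnorm(n, sd = read_noise_sigma)
  matrix(noisy, nrow(mat), ncol(mat))
}

scene_grid <- function(spec) {
  c(ny = round(spec$field_size[2] / spec$pixel_size),
    nx = round(spec$field_size[1] / spec$pixel_size))
}

new_ground_truth <- function(centers, spec, ...) {
  structure(c(list(
    centers = data.frame(x_um = centers[, 1], y_um = centers[, 2]),
    cluster_labels = single_linkage_labels(centers, 2.0),
    true_core_fwhm = gaussian_fwhm(spec$core_sigma),
    true_ring_diameter = 2 * spec$ring_radius
  ), list(...)), class = "ground_truth")
}

render_channel <- function(spec, centers, channel, ny, nx, amplitudes = NULL) {
  amp <- amplitudes %||% rep(spec$channel_amplitudes[[channel]], nrow(centers))
  if (identical(channel, "core")) {
    render_spots(ny, nx, spec$pixel_size, centers, amp, spec$core_sigma)
  } else {
    render_spots(ny, nx, spec$pixel_size, centers, amp, spec$ring_sigma,
                 ring_radius = spec$ring_radius)
  }
}

#' Simulate a multichannel podosome cluster image
#'
#' Places `n_podosomes` centers by hard-core rejection sampling and renders
#' the `"core"` channel as isotropic Gaussians and every other named channel
#' as Gaussian annuli peaking at `ring_radius`. The noiseless scene is
#' blurred with a normalized Gaussian PSF, then Poisson shot noise and
#' Gaussian read noise are added.
#'
#' @param spec a [scene_spec()].
#' @param noise add camera noise (set `FALSE` for noiseless ground truth).
#' @return `list(image = image_series, truth = ground_truth)`.
#' @export
simulate_cluster_image <- function(spec, noise = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  g <- scene_grid(spec)
  withr::with_seed(spec$seed, {
    centers <- place_hardcore(spec$n_podosomes, spec$field_size,
                              spec$min_separation, spec$margin)
    chans <- names(spec$channel_amplitudes)
    arr <- array(0, dim = c(1, 1, length(chans), g["ny"], g["nx"]))
    for (k in seq_along(chans)) {
      m <- render_channel(spec, centers, chans[k], g["ny"], g["nx"]) +
        spec$background
      m <- fft_gaussian_blur(m, spec$psf_sigma / spec$pixel_size)
      if (noise) m <- add_camera_noise(m, spec$read_noise_sigma)
      arr[1, 1, k, , ] <- m
    }
  })
  img <- image_series(arr, spec$pixel_size, channels = chans)
  list(image = img, truth = new_ground_truth(centers, spec))
}

#' Simulate a podosome z-stack
#'
#' Core and ring intensity concentrate at the ventral plane; a dorsal
#' (myosin-like) channel concentrates at `dorsal_z`, placed as an annulus of
#' radius `dorsal_radius` (0.8-0.9 um) around each core. Axial profiles are
#' Gaussian with width `z_sigma`.
#'
#' @param spec a [scene_spec()].
#' @param z_step z spacing, um (> 0).
#' @param ventral_z,dorsal_z axial positions of the ventral and dorsal
#'   structures, um (`dorsal_z > ventral_z`).
#' @param z_max top of the acquired range, um; default `dorsal_z + 0.4`.
#'   An error is raised if the range does not cover `dorsal_z`.
#' @param z_sigma axial Gaussian width of each structure, um.
#' @param dorsal_radius radial offset of the dorsal annulus from the core
#'   center, um.
#' @param noise add camera noise.
#' @return `list(image = image_series, truth = ground_truth)`; the truth
#'   carries `true_z_heights` per channel.
#' @export
simulate_zstack <- function(spec, z_step = 0.1, ventral_z = 0, dorsal_z = 0.5,
                            z_max = NULL, z_sigma = 0.15, dorsal_radius = 0.85,
                            noise = TRUE) {
  stopifnot(inherits(spec, "scene_spec"), z_step > 0, dorsal_z > ventral_z)
  z_max <- z_max %||% (dorsal_z + 0.4)
  z_axis <- seq(ventral_z, z_max, by = z_step)
  if (max(z_axis) < dorsal_z) {
    stop(sprintf("z range [%.3g, %.3g] um does not cover dorsal_z = %.3g um",
                 ventral_z, max(z_axis), dorsal_z))
  }
  g <- scene_grid(spec)
  nz <- length(z_axis)
  amp_of <- function(ch, default) {
    if (ch %in% names(spec$channel_amplitudes)) spec$channel_amplitudes[[ch]]
    else default
  }
  chans <- c("core", "ring", "myosin")
  z_heights <- c(core = ventral_z, ring = ventral_z, myosin = dorsal_z)
  withr::with_seed(spec$seed, {
    centers <- place_hardcore(spec$n_podosomes, spec$field_size,
                              spec$min_separation, spec$margin)
    base <- list(
      core = render_spots(g["ny"], g["nx"], spec$pixel_size, centers,
                          amp_of("core", 120), spec$core_sigma),
      ring = render_spots(g["ny"], g["nx"], spec$pixel_size, centers,
                          amp_of("ring", 100), spec$ring_sigma,
                          ring_radius = spec$ring_radius),
      myosin = render_spots(g["ny"], g["nx"], spec$pixel_size, centers,
                            amp_of("myosin", 100), spec$ring_sigma,
                            ring_radius = dorsal_radius)
    )
    arr <- array(0, dim = c(1, nz, length(chans), g["ny"], g["nx"]))
    for (k in seq_along(chans)) {
      for (iz in seq_len(nz)) {
        w <- exp(-(z_axis[iz] - z_heights[[chans[k]]])^2 / (2 * z_sigma^2))
        m <- base[[chans[k]]] * w + spec$background
        m <- fft_gaussian_blur(m, spec$psf_sigma / spec$pixel_size)
        if (noise) m <- add_camera_noise(m, spec$read_noise_sigma)
        arr[1, iz, k, , ] <- m
      }
    }
  })
  img <- image_series(arr, spec$pixel_size, z_step = z_step, channels = chans)
  truth <- new_ground_truth(centers, spec,
                            true_z_heights = z_heights, z_axis = z_axis,
                            z_sigma = z_sigma, dorsal_radius = dorsal_radius)
  list(image = img, truth = truth)
}

#' Simulate an oscillating / drifting podosome time-lapse
#'
#' Each podosome's core intensity is modulated sinusoidally with a phase
#' drawn from a Gaussian random field correlated over
#' `flow$correlation_length`; the same phase drives a small lateral
#' oscillation along a direction field correlated at the same scale
#' (amplitude `flow$wobble_amplitude`), so that vertical oscillations
#' translate into locally coherent lateral flows. A uniform
#' `drift_velocity` (um/min) can be superimposed; `immobile_fraction` of
#' each podosome's intensity stays static.
#'
#' @param spec a [scene_spec()] (placement, geometry, photon budget).
#' @param flow a [flow_spec()].
#' @param noise add per-frame camera noise.
#' @return `list(image = image_series, truth = ground_truth)`; the truth
#'   carries `oscillation_phase` (rad), `phase_latent` (the underlying
#'   standardized field values), `wobble_dirs` and, for the drift case,
#'   `true_velocity_field` (um/min per podosome).
#' @export
simulate_flow_series <- function(spec, flow, noise = TRUE) {
  stopifnot(inherits(spec, "scene_spec"), inherits(flow, "flow_spec"))
  g <- scene_grid(spec)
  amp_core <- spec$channel_amplitudes[["core"]]
  withr::with_seed(spec$seed, {
    centers <- place_hardcore(spec$n_podosomes, spec$field_size,
                              spec$min_separation, spec$margin)
  })
  n <- nrow(centers)
  nt <- flow$n_frames
  withr::with_seed(flow$seed, {
    if (n > 0) {
      fields <- grf_at_points(centers, flow$correlation_length, n_fields = 3)
      phase_latent <- fields[, 1]
      phases <- flow$phase_dispersion * phase_latent
      # unit directions: spatially correlated orientation, fixed amplitude
      wobble_dirs <- fields[, 2:3, drop = FALSE]
      nrm <- sqrt(rowSums(wobble_dirs^2))
      nrm[nrm < 1e-12] <- 1
      wobble_dirs <- wobble_dirs / nrm
    } else {
      phase_latent <- numeric(0)
      phases <- numeric(0)
      wobble_dirs <- matrix(numeric(0), 0, 2)
    }
    # granular core texture: sub-resolution speckles at fixed offsets within
    # the Gaussian core envelope, moving rigidly with the podosome; total
    # intensity matches the smooth core of the same amplitude
    k <- flow$texture_n
    if (k > 0 && n > 0) {
      tex_off <- matrix(rnorm(n * k * 2, sd = spec$core_sigma), n * k, 2)
      smooth_integral <- 2 * pi * (spec$core_sigma / spec$pixel_size)^2
      speck_integral <- 2 * pi * (flow$texture_sigma / spec$pixel_size)^2
      tex_amp0 <- runif(n * k, 0.5, 1.5)
      tex_amp0 <- tex_amp0 * smooth_integral / (k * speck_integral)
    }
    render_cores <- function(pos, amp) {
      if (k == 0 || n == 0) {
        return(render_spots(g["ny"], g["nx"], spec$pixel_size, pos, amp,
                            spec$core_sigma))
      }
      pos_k <- pos[rep(seq_len(n), each = k), , drop = FALSE] + tex_off
      amp_k <- rep(amp, each = k) * tex_amp0
      render_spots(g["ny"], g["nx"], spec$pixel_size, pos_k, amp_k,
                   flow$texture_sigma)
    }
    n_net <- round(flow$network_density * prod(spec$field_size))
    if (n_net > 0) {
      net_pos <- cbind(runif(n_net, 0, spec$field_size[1]),
                       runif(n_net, 0, spec$field_size[2]))
      net_amp <- flow$network_amplitude * runif(n_net, 0.5, 1.5)
    }
    static_amp <- rep(amp_core * flow$immobile_fraction, n)
    mobile_amp0 <- amp_core * (1 - flow$immobile_fraction)
    static_img <- render_cores(centers, static_amp)
    arr <- array(0, dim = c(nt, 1, 1, g["ny"], g["nx"]))
    for (t in seq_len(nt)) {
      time_s <- (t - 1) * flow$frame_interval
      osc <- sin(2 * pi * time_s / flow$oscillation_period + phases)
      amp_t <- mobile_amp0 * (1 + flow$oscillation_amplitude * osc)
      pos_t <- centers
      if (n > 0) {
        pos_t <- centers +
          matrix(flow$drift_velocity * (time_s / 60), n, 2, byrow = TRUE) +
          flow$wobble_amplitude * wobble_dirs * osc
      }
      m <- static_img + render_cores(pos_t, rep_len(amp_t, n)) +
        spec$background
      if (n_net > 0) {
        net_t <- net_pos +
          matrix(flow$drift_velocity * (time_s / 60), n_net, 2, byrow = TRUE)
        m <- m + render_spots(g["ny"], g["nx"], spec$pixel_size, net_t,
                              net_amp, flow$texture_sigma)
      }
      m <- fft_gaussian_blur(m, spec$psf_sigma / spec$pixel_size)
      if (noise) m <- add_camera_noise(m, spec$read_noise_sigma)
      arr[t, 1, 1, , ] <- m
    }
  })
  img <- image_series(arr, spec$pixel_size,
                      frame_interval = flow$frame_interval,
                      channels = "core")
  truth <- new_ground_truth(
    centers, spec,
    oscillation_phase = phases, phase_latent = phase_latent,
    wobble_dirs = wobble_dirs,
    true_velocity_field = data.frame(
      vx = rep(flow$drift_velocity[1], n),
      vy = rep(flow$drift_velocity[2], n))
  )
  list(image = img, truth = truth)
}

#' Simulate a rhodamine-gelatin degradation field
#'
#' A uniform labeled-gelatin layer in which `degraded_fraction` of the
#' cell-footprint pixels lose `degradation_depth` of their intensity. The
#' degraded region is a spatially coherent random patch set (thresholded
#' smoothed noise) so that it resembles podosome-driven matrix lysis rather
#' than salt-and-pepper dropout.
#'
#' @param spec a [scene_spec()] (field geometry, photon budget, seed).
#' @param degraded_fraction fraction of cell-footprint pixels degraded.
#' @param degradation_depth fractional intensity loss in degraded pixels.
#' @param gelatin_amplitude intact gelatin intensity, photons.
#' @param cell_radius footprint radius, um; default 0.35 x min(field).
#' @param noise add camera noise.
#' @return `list(image, truth)`; the truth carries `cell_mask`,
#'   `reference_mask` and `true_degraded_mask` (logical (Y, X) matrices).
#' @export
simulate_gelatin_assay <- function(spec, degraded_fraction = 0.2,
                                   degradation_depth = 1,
                                   gelatin_amplitude = 100,
                                   cell_radius = NULL, noise = TRUE) {
  stopifnot(inherits(spec, "scene_spec"),
            degraded_fraction >= 0, degraded_fraction <= 1,
            degradation_depth >= 0, degradation_depth <= 1)
  g <- scene_grid(spec)
  px <- spec$pixel_size
  cell_radius <- cell_radius %||% (0.35 * min(spec$field_size))
  cx <- spec$field_size[1] / 2
  cy <- spec$field_size[2] / 2
  xs <- (0:(g["nx"] - 1)) * px
  ys <- (0:(g["ny"] - 1)) * px
  r2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  cell_mask <- r2 <= cell_radius^2
  reference_mask <- r2 >= (cell_radius + 0.5)^2
  withr::with_seed(spec$seed, {
    degraded <- matrix(FALSE, g["ny"], g["nx"])
    if (degraded_fraction > 0) {
      field <- fft_gaussian_blur(matrix(rnorm(g["ny"] * g["nx"]),
                                        g["ny"], g["nx"]), 0.3 / px)
      vals <- field[cell_mask]
      cut <- quantile(vals, probs = 1 - degraded_fraction, names = FALSE)
      degraded <- cell_mask & (field >= cut)
    }
    m <- matrix(gelatin_amplitude, g["ny"], g["nx"])
    m[degraded] <- m[degraded] * (1 - degradation_depth)
    if (noise) m <- add_camera_noise(m, spec$read_noise_sigma)
  })
  img <- image_series(array(m, dim = c(1, 1, 1, g["ny"], g["nx"])), px,
                      channels = "gelatin")
  truth <- structure(list(
    cell_mask = cell_mask,
    reference_mask = reference_mask,
    true_degraded_mask = degraded,
    degraded_fraction = degraded_fraction,
    degradation_depth = degradation_depth
  ), class = "ground_truth")
  list(image = img, truth = truth)
}
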