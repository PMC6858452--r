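# Canonical study conditions: the synthetic scenes and configurations used
# by the analysis scripts and the validation suites. Freezing them here
# keeps every consumer (tests, drivers, reproduction script) on identical
# conditions.

#' Canonical morphometry recovery scene
#'
#' 100 podosomes in a 20 x 20 um field at the imaging regime the package
#' emulates: apparent core FWHM 0.40 um, ring diameter 0.77 um
#' (alpha-actinin / gamma-actin scale), 0.04 um pixels, peak SNR ~ 10.
#'
#' @param seed integer seed.
#' @param ring_radius ring peak radius, um (0.51 gives a vinculin-like
#'   1.02 um ring).
#' @return A [scene_spec()].
#' @export
morphometry_scene <- function(seed = 1L, ring_radius = 0.385) {
  scene_spec(field_size = c(20, 20), n_podosomes = 100,
             min_separation = 1.5, ring_radius = ring_radius,
             margin = 1.0, seed = seed)
}

#' Canonical height-analysis stack
#'
#' 100-podosome z-stack with the dorsal (myosin-like) plane at 0.47 um and
#' 0.1 um z-steps.
#'
#' @param seed integer seed.
#' @param dorsal_z dorsal plane height, um.
#' @return `list(image, truth)` from [simulate_zstack()].
#' @export
height_stack <- function(seed = 1L, dorsal_z = 0.47) {
  sp <- scene_spec(field_size = c(20, 20), n_podosomes = 100,
                   min_separation = 1.5, margin = 1.0, seed = seed)
  simulate_zstack(sp, z_step = 0.1, dorsal_z = dorsal_z)
}

#' Canonical oscillating-cluster movie for one stiffness regime
#'
#' 14 podosomes in a 6.4 x 6.4 um field, 20 frames at 15 s, intensity
#' oscillation (amplitude 0.3, period 360 s) with phases and lateral
#' oscillation directions drawn from a Gaussian random field of scale
#' `correlation_length`: 2.5 um emulates the soft-substrate regime, 10 um
#' the stiff-substrate regime. Core amplitude 250 photons (bright live-cell
#' label) so the oscillation residual is well above shot noise.
#'
#' @param regime `"soft"` or `"stiff"` (sets the correlation length), or
#'   use `correlation_length` directly.
#' @param seed integer seed.
#' @param correlation_length override of the phase-field scale, um.
#' @param drift_velocity `(vx, vy)` um/min superimposed drift.
#' @param wobble_amplitude lateral oscillation amplitude, um.
#' @param n_frames movie length, frames.
#' @return `list(image, truth)` from [simulate_flow_series()].
#' @export
regime_movie <- function(regime = c("soft", "stiff"), seed = 1L,
                         correlation_length = NULL,
                         drift_velocity = c(0, 0),
                         wobble_amplitude = 0.12, n_frames = 20) {
  if (is.null(correlation_length)) {
    regime <- match.arg(regime)
    correlation_length <- if (regime == "soft") 2.5 else 10
  }
  sp <- scene_spec(field_size = c(6.4, 6.4), n_podosomes = 14,
                   min_separation = 1.0, margin = 0.7,
                   channel_amplitudes = c(core = 250), seed = seed)
  fl <- flow_spec(n_frames = n_frames, oscillation_amplitude = 0.3,
                  wobble_amplitude = wobble_amplitude,
                  oscillation_period = 360,
                  correlation_length = correlation_length,
                  drift_velocity = drift_velocity, seed = seed + 1000L)
  simulate_flow_series(sp, fl)
}

#' Canonical twSTICS configuration for the synthetic movies
#'
#' The published ROI/TOI protocol (16-px ROIs, 10-frame TOIs, 0.04 um
#' pixels, 15 s frames) with the oversampling reduced for replicate sweeps:
#' ROI stride 8 px and TOI stride 5 frames, correlation fitted over lags
#' 1..5.
#'
#' @return A [stics_config()].
#' @export
movie_stics_config <- function() {
  stics_config(roi_size = 16, roi_shift = 8, toi_length = 10, toi_shift = 5,
               max_tau = 5, pixel_size = 0.04, frame_interval = 15)
}

#' twSTICS + PVC chain for one movie
#'
#' @param sim result of [regime_movie()] (or any flow simulation).
#' @param config a [stics_config()].
#' @param max_dr largest PVC separation, um.
#' @return `list(field, pvc, extent)`; `extent` is `NA` when fewer than two
#'   vectors survive filtering.
#' @export
movie_connectivity <- function(sim, config = movie_stics_config(),
                               max_dr = 4.8) {
  field <- suppressWarnings(stics_vector_field(sim$image, config))
  if (sum(field$retained) < 2) {
    return(list(field = field, pvc = NULL, extent = NA_real_))
  }
  pvc <- pair_vector_correlation(field, max_dr = max_dr,
                                 max_dt = max(field$toi) - 1)
  ext <- tryCatch(correlation_extent(pvc)$spatial_extent_um,
                  error = function(e) NA_real_)
  list(field = field, pvc = pvc, extent = ext)
}

#' Noiseless translating validation lattice
#'
#' A jittered-amplitude lattice of fine Gaussian spots (8 px spacing,
#' sigma 1 px) rendered analytically at positions translated by
#' `drift_px_frame` per frame, so that every 16 x 16 ROI contains clean
#' trackable structure. This is the end-to-end translation oracle for the
#' velocity chain; podosome-sized blobs in 16-px windows carry a
#' window-truncation bias of order 10% that this scene deliberately avoids
#' (see the methods vignette).
#'
#' @param drift_px_frame `(dx, dy)` px/frame.
#' @param n_frames frames.
#' @param n_px field size, px.
#' @param seed seed for the amplitude jitter.
#' @param pixel_size um/px.
#' @return A (T, Y, X) array.
#' @export
translation_lattice <- function(drift_px_frame = c(0.3, -0.2), n_frames = 12,
                                n_px = 96, seed = 11L, pixel_size = 0.04) {
  withr::with_seed(seed, {
    g <- seq(4, n_px - 4, by = 8)
    pts <- as.matrix(expand.grid(x = g * pixel_size, y = g * pixel_size))
    amp <- runif(nrow(pts), 80, 150)
  })
  arr <- array(0, c(n_frames, n_px, n_px))
  for (t in seq_len(n_frames)) {
    sh <- cbind(pts[, 1] + drift_px_frame[1] * (t - 1) * pixel_size,
                pts[, 2] + drift_px_frame[2] * (t - 1) * pixel_size)
    arr[t, , ] <- render_spots(n_px, n_px, pixel_size, sh, amp,
                               1.0 * pixel_size)
  }
  arr
}

#' Canonical drift-recovery movie
#'
#' Synchronized oscillating cluster (phase correlation length much larger
#' than the field, so blinking adds no lateral flows) with a uniform
#' imposed drift at the physiological velocity scale.
#'
#' @param seed integer seed.
#' @param speed drift speed, um/min (applied along the diagonal).
#' @return `list(image, truth, config)`.
#' @export
drift_movie <- function(seed = 31L, speed = 0.05) {
  sp <- scene_spec(field_size = c(5.12, 5.12), n_podosomes = 9,
                   min_separation = 1.0, margin = 0.7, seed = seed)
  fl <- flow_spec(n_frames = 25, oscillation_amplitude = 0.3,
                  wobble_amplitude = 0, correlation_length = 50,
                  drift_velocity = speed * c(1, 1) / sqrt(2),
                  network_density = 3, seed = seed + 1L)
  sim <- simulate_flow_series(sp, fl)
  # no static structures exist in this scene (cluster and network drift
  # together), so the immobile filter would only subtract a drift-smeared
  # streak that biases the correlation peak; the search window keeps
  # structure visible as it leaves each ROI
  cfg <- stics_config(roi_size = 16, roi_shift = 8, toi_length = 10,
                      toi_shift = 5, max_tau = 9, pixel_size = 0.04,
                      frame_interval = 15, immobile_modes_removed = 0,
                      search_pad = 6)
  c(sim, list(config = cfg))
}
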