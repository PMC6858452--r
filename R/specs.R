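#' Synthetic podosome scene specification
#'
#' Parameters of the still-image generator. Defaults emulate the geometry and
#' imaging regime of Airyscan podosome data: cores of apparent FWHM 0.40 um
#' (`core_sigma` 0.17 um), adaptor rings peaking at 0.385 um radius (ring
#' diameter 0.77 um, the alpha-actinin / gamma-actin scale; use
#' `ring_radius = 0.51` for a vinculin-like 1.02 um ring), 0.04 um pixels, and
#' photon counts giving a peak signal-to-noise ratio of about 10
#' (`SNR = A / sqrt(A + background + read_noise_sigma^2)`).
#'
#' @param field_size field of view `(x, y)` in um.
#' @param pixel_size lateral pixel size, um.
#' @param n_podosomes number of podosomes to place.
#' @param min_separation hard-core distance between centers, um.
#' @param core_sigma Gaussian sigma of the core (cPM) channel, um.
#' @param ring_radius radius of peak ring (pPM/vinculin) intensity, um.
#' @param ring_sigma Gaussian width of the ring annulus, um.
#' @param channel_amplitudes named per-channel peak intensities (photons).
#'   The channel named `"core"` is rendered as an isotropic Gaussian; all
#'   other channels as Gaussian annuli at `ring_radius`.
#' @param background uniform background level, photons.
#' @param psf_sigma residual optical blur applied to the noiseless scene, um.
#' @param read_noise_sigma Gaussian read noise sigma, photons.
#' @param margin minimum distance of centers from the field edge, um.
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return A validated `scene_spec` object.
#' @export
scene_spec <- function(field_size = c(10, 10), pixel_size = 0.04,
                       n_podosomes = 20, min_separation = 1.0,
                       core_sigma = 0.17, ring_radius = 0.385,
                       ring_sigma = 0.10,
                       channel_amplitudes = c(core = 120, ring = 100),
                       background = 10, psf_sigma = 0.04,
                       read_noise_sigma = 3, margin = 1.0, seed = 1L) {
  field_size <- rep_len(as.numeric(field_size), 2)
  stopifnot(all(field_size > 0), pixel_size > 0, min_separation > 0,
            core_sigma > 0, ring_radius >= 0, ring_sigma > 0,
            background >= 0, psf_sigma >= 0, read_noise_sigma >= 0,
            n_podosomes >= 0, margin >= 0)
  if (is.null(names(channel_amplitudes)) || anyDuplicated(names(channel_amplitudes)))
    stop("channel_amplitudes must be uniquely named")
  if (any(channel_amplitudes < 0)) stop("channel_amplitudes must be >= 0")
  structure(list(
    field_size = field_size, pixel_size = pixel_size,
    n_podosomes = as.integer(n_podosomes), min_separation = min_separation,
    core_sigma = core_sigma, ring_radius = ring_radius, ring_sigma = ring_sigma,
    channel_amplitudes = channel_amplitudes, background = background,
    psf_sigma = psf_sigma, read_noise_sigma = read_noise_sigma,
    margin = margin, seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Time-lapse flow specification
#'
#' Parameters of the oscillating / drifting time-lapse generator. Podosome
#' intensities are modulated sinusoidally with per-podosome phases drawn from
#' a Gaussian random field with squared-exponential covariance of scale
#' `correlation_length`; this single knob reproduces the stiff-substrate
#' (phase coherence over ~10 um) versus soft-substrate (2-3 um) connectivity
#' regimes. A lateral oscillation (`wobble_amplitude`) with spatially
#' correlated directions converts the vertical oscillation into the locally
#' coherent intensity flows that twSTICS measures; a uniform `drift_velocity`
#' can be superimposed as a known translation ground truth.
#'
#' @param frame_interval s between frames (15 s is the acquisition default).
#' @param n_frames number of frames (>= 2).
#' @param oscillation_period s per oscillation cycle.
#' @param oscillation_amplitude fractional intensity modulation in `[0, 1]`.
#' @param correlation_length um; spatial scale over which oscillation phases
#'   (and wobble directions) are shared.
#' @param phase_dispersion standard deviation of the per-podosome
#'   oscillation phase, rad; phases are `phase_dispersion` times a unit
#'   Gaussian random field, so nearby podosomes stay coherent while the
#'   coherence between distant podosomes falls off over
#'   `correlation_length`.
#' @param drift_velocity `(vx, vy)` um/min uniform translation of the mobile
#'   intensity.
#' @param immobile_fraction fraction of podosome intensity that stays static.
#' @param wobble_amplitude um; amplitude of the correlated lateral
#'   oscillation of podosome positions (0 disables it).
#' @param texture_n sub-resolution speckles rendered per podosome core
#'   (0 gives a smooth Gaussian). Live actin labels resolve granular
#'   internal texture that moves rigidly with the core; correlation
#'   tracking relies on it, and smooth Gaussians are measurably harder to
#'   track (see the methods vignette).
#' @param texture_sigma speckle Gaussian sigma, um.
#' @param network_density diffuse actin-network speckles per um^2 rendered
#'   across the whole field (0 disables). The network moves with
#'   `drift_velocity` but does not oscillate; it emulates the
#'   interpodosomal / cortical F-actin a live label also stains.
#' @param network_amplitude peak intensity of one network speckle, photons.
#' @param seed integer seed for phases, directions and noise.
#' @return A validated `flow_spec` object.
#' @export
flow_spec <- function(frame_interval = 15, n_frames = 20,
                      oscillation_period = 300, oscillation_amplitude = 0.3,
                      correlation_length = 2.5, phase_dispersion = 2,
                      drift_velocity = c(0, 0),
                      immobile_fraction = 0, wobble_amplitude = 0.05,
                      texture_n = 15L, texture_sigma = 0.06,
                      network_density = 0, network_amplitude = 30,
                      seed = 1L) {
  drift_velocity <- rep_len(as.numeric(drift_velocity), 2)
  stopifnot(frame_interval > 0, n_frames >= 2, oscillation_period > 0,
            oscillation_amplitude >= 0, oscillation_amplitude <= 1,
            correlation_length > 0, phase_dispersion >= 0,
            immobile_fraction >= 0, immobile_fraction <= 1,
            wobble_amplitude >= 0, texture_n >= 0, texture_sigma > 0,
            network_density >= 0, network_amplitude >= 0)
  structure(list(
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    oscillation_period = oscillation_period,
    oscillation_amplitude = oscillation_amplitude,
    correlation_length = correlation_length,
    phase_dispersion = phase_dispersion,
    drift_velocity = drift_velocity,
    immobile_fraction = immobile_fraction,
    wobble_amplitude = wobble_amplitude,
    texture_n = as.integer(texture_n), texture_sigma = texture_sigma,
    network_density = network_density,
    network_amplitude = network_amplitude,
    seed = as.integer(seed)
  ), class = "flow_spec")
}
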