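# Rotating-line radial intensity profiling and Gaussian profile fits.

#' Angularly averaged radial intensity profile
#'
#' Draws a two-sided line of total length `2 * half_length` through the
#' podosome center, rotates it over `n_angles` uniformly spaced orientations
#' in `[0, pi)`, samples the intensity along each line by bilinear
#' interpolation at pixel-size steps, and returns the per-distance mean over
#' angles. Samples falling outside the image are clipped (dropped from the
#' angular mean) and the profile is flagged `clipped`.
#'
#' @param image an [image_series()] or matrix.
#' @param center `(x, y)` position in um (sub-pixel allowed).
#' @param half_length half line length, um (the acquisition convention is a
#'   line of ~3 um, i.e. `half_length = 1.5`).
#' @param n_angles number of line orientations (>= 1).
#' @param channel,t,z plane selectors.
#' @param pixel_size required for matrix input.
#' @return A `radial_profile` object: `distances` (um, symmetric about 0),
#'   `mean_intensity`, `dispersion` (s.d. across angles),
#'   `dispersion_type`, `n_podosomes`, `n_angles`, `normalized`, `clipped`.
#' @export
radial_profile <- function(image, center, half_length = 1.5, n_angles = 180,
                           channel = 1, t = 1, z = 1, pixel_size = NULL) {
  if (inherits(image, "image_series")) {
    m <- get_plane(image, channel, t, z)
    px <- image$pixel_size
  } else {
    m <- as.matrix(image)
    px <- pixel_size
    if (is.null(px)) stop("pixel_size required for matrix input")
  }
  stopifnot(length(center) == 2, n_angles >= 1, half_length > 0)
  cx <- center[1] / px
  cy <- center[2] / px
  if (cx < 0 || cx > ncol(m) - 1 || cy < 0 || cy > nrow(m) - 1) {
    stop("center lies outside the image")
  }
  k <- round(half_length / px)
  d_px <- -k:k
  angles <- (seq_len(n_angles) - 1) * pi / n_angles
  xs <- cx + outer(d_px, cos(angles))
  ys <- cy + outer(d_px, sin(angles))
  samples <- matrix(bilinear_sample(m, as.vector(xs), as.vector(ys)),
                    length(d_px), n_angles)
  clipped <- anyNA(samples)
  mean_i <- rowMeans(samples, na.rm = TRUE)
  disp <- apply(samples, 1, sd, na.rm = TRUE)
  structure(list(
    distances = d_px * px,
    mean_intensity = mean_i,
    dispersion = disp,
    dispersion_type = "sd_over_angles",
    n_podosomes = 1L,
    n_angles = as.integer(n_angles),
    normalized = FALSE,
    clipped = clipped
  ), class = "radial_profile")
}

#' Average radial profiles over podosomes
#'
#' Pointwise mean over a list of profiles sharing one distance grid, with
#' the across-podosome standard deviation as dispersion. Min-max
#' normalization is presentation-only: fits should run on unnormalized
#' averages because normalizing first distorts the offset estimate.
#'
#' @param profiles list of [radial_profile()] results on a common grid.
#' @param normalize min-max scale the averaged profile to `[0, 1]`.
#' @return A `radial_profile` object with `n_podosomes = length(profiles)`.
#' @export
average_profiles <- function(profiles, normalize = FALSE) {
  if (length(profiles) == 0) stop("empty profile list")
  stopifnot(all(vapply(profiles, inherits, logical(1), "radial_profile")))
  d0 <- profiles[[1]]$distances
  same <- vapply(profiles, function(p) {
    length(p$distances) == length(d0) && all(abs(p$distances - d0) < 1e-9)
  }, logical(1))
  if (!all(same)) stop("profiles do not share a common distance grid")
  mat <- vapply(profiles, `[[`, numeric(length(d0)), "mean_intensity")
  mat <- matrix(mat, nrow = length(d0))
  avg <- rowMeans(mat)
  disp <- if (ncol(mat) > 1) apply(mat, 1, sd) else rep(0, length(d0))
  if (normalize) {
    rng <- range(avg)
    if (diff(rng) > 0) avg <- (avg - rng[1]) / diff(rng)
  }
  structure(list(
    distances = d0,
    mean_intensity = avg,
    dispersion = disp,
    dispersion_type = "sd_over_podosomes",
    n_podosomes = length(profiles),
    n_angles = profiles[[1]]$n_angles,
    normalized = isTRUE(normalize),
    clipped = any(vapply(profiles, `[[`, logical(1), "clipped"))
  ), class = "radial_profile")
}

profile_fit_result <- function(model, pars, r2, converged, note = NA_character_) {
  pars <- as.list(pars)
  if (is.null(pars$R)) pars$R <- 0
  fwhm <- gaussian_fwhm(pars[["sigma"]])
  structure(list(
    model = model,
    amplitude = pars[["A"]],
    center_r = pars[["R"]],
    sigma = pars[["sigma"]],
    offset = pars[["c"]],
    fwhm = fwhm,
    diameter = if (model == "mirrored-annulus") 2 * pars[["R"]] else NA_real_,
    r_squared = r2,
    accepted = converged && fit_accepted(r2),
    converged = converged,
    note = note
  ), class = "profile_fit")
}

# The acceptance rule is strict: R^2 must exceed 0.95; a fit exactly at the
# boundary is rejected.
fit_accepted <- function(r2) is.finite(r2) && r2 > 0.95

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("<profile_fit:%s> fwhm=%.4f um%s R2=%.4f %s\n", x$model, x$fwhm,
              if (!is.na(x$diameter)) sprintf(" diameter=%.4f um", x$diameter) else "",
              x$r_squared, if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Gaussian fit of a radial profile
#'
#' Nonlinear least squares on the (unnormalized) two-sided profile.
#' `"single-gaussian-offset"` fits `A exp(-r^2 / (2 sigma^2)) + c`;
#' `"mirrored-annulus"` fits the symmetric two-peak model
#' `A [exp(-(r - R)^2 / (2 sigma^2)) + exp(-(r + R)^2 / (2 sigma^2))] + c`,
#' whose ring diameter is the peak-to-peak distance `2 R`. Fits that do not
#' converge are returned with `accepted = FALSE` and a diagnostic note;
#' fitted widths are bounded positive. Acceptance requires `R^2 > 0.95`
#' (strict).
#'
#' @param profile a [radial_profile()].
#' @param model `"single-gaussian-offset"` or `"mirrored-annulus"`.
#' @return A `profile_fit` object with `fwhm = 2 sqrt(2 ln 2) sigma`,
#'   `diameter` (annulus only), `r_squared` and the `accepted` flag.
#' @export
fit_gaussian_profile <- function(profile,
                                 model = c("single-gaussian-offset",
                                           "mirrored-annulus")) {
  model <- match.arg(model)
  stopifnot(inherits(profile, "radial_profile"))
  r <- profile$distances
  y <- profile$mean_intensity
  ok <- is.finite(r) & is.finite(y)
  r <- r[ok]; y <- y[ok]
  if (length(r) < 6) stop("profile needs at least 6 finite points")
  span <- max(r) - min(r)
  amp0 <- max(y) - min(y)
  if (amp0 <= 0) {
    return(profile_fit_result(model, c(A = 0, R = 0, sigma = span / 4,
                                       c = mean(y)),
                              r2 = 0, converged = FALSE, note = "flat profile"))
  }
  sst <- sum((y - mean(y))^2)
  fit <- tryCatch({
    if (model == "single-gaussian-offset") {
      nlsLM(y ~ A * exp(-r^2 / (2 * sigma^2)) + c,
            start = list(A = amp0, sigma = span / 8, c = min(y)),
            lower = c(A = 0, sigma = 1e-4, c = -Inf),
            upper = c(A = Inf, sigma = span, c = Inf),
            control = nls.lm.control(maxiter = 200))
    } else {
      R0 <- abs(r[which.max(y)])
      if (R0 < span / 20) R0 <- span / 8
      nlsLM(y ~ A * (exp(-(r - R)^2 / (2 * sigma^2)) +
                       exp(-(r + R)^2 / (2 * sigma^2))) + c,
            start = list(A = amp0 / 2, R = R0, sigma = span / 16, c = min(y)),
            lower = c(A = 0, R = 0, sigma = 1e-4, c = -Inf),
            upper = c(A = Inf, R = max(abs(r)), sigma = span, c = Inf),
            control = nls.lm.control(maxiter = 200))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    pars <- if (model == "single-gaussian-offset") {
      c(A = amp0, R = 0, sigma = span / 8, c = min(y))
    } else {
      c(A = amp0 / 2, R = span / 8, sigma = span / 16, c = min(y))
    }
    return(profile_fit_result(model, pars, r2 = NA_real_, converged = FALSE,
                              note = conditionMessage(fit)))
  }
  cf <- coef(fit)
  if (!("R" %in% names(cf))) cf[["R"]] <- 0
  r2 <- if (sst > 0) 1 - sum(resid(fit)^2) / sst else NA_real_
  profile_fit_result(model, as.list(cf), r2 = r2, converged = TRUE)
}

#' Ring diameter from a mirrored-annulus fit
#'
#' Convenience wrapper around [fit_gaussian_profile()] with the
#' mirrored-annulus model; the ring diameter is the distance between the two
#' fitted peak centers (`2 R`). A degenerate fit with `R` collapsing to 0
#' reduces to a single Gaussian and is reported with a warning.
#'
#' @param profile a [radial_profile()].
#' @return A `profile_fit` with the `diameter` field populated.
#' @export
ring_diameter <- function(profile) {
  fit <- fit_gaussian_profile(profile, model = "mirrored-annulus")
  if (isTRUE(fit$converged) && fit$diameter < fit$sigma / 2) {
    warning("annulus fit degenerate: R ~ 0, profile is effectively a single Gaussian")
  }
  fit
}
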