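# Sliding-time-window spatiotemporal image correlation spectroscopy
# (twSTICS): immobile filtering, ROI/TOI tiling, space-time correlation,
# Gaussian correlation-peak tracking and velocity estimation.

#' twSTICS configuration
#'
#' Defaults follow the published analysis protocol: 16 x 16 px ROIs
#' (0.64 x 0.64 um at 0.04 um pixels) shifted 4 px for 75% spatial overlap,
#' 10-frame TOIs (2.5 min at 15-s frames) shifted one frame for 90%
#' temporal overlap, correlation fit over time lags up to `max_tau`
#' (capped at `toi_length - 1`, the largest lag available inside a TOI).
#' The immobile filter removes the `immobile_modes_removed` lowest temporal
#' frequencies per pixel (1 = the DC component). `tau_min = 1` excludes the
#' lag-0 correlation, whose peak carries the white-noise spike, from the
#' velocity fit; the free intercept of the lag fit absorbs any residual
#' offset. The similarity criterion (angle within `max_angle_deg`,
#' magnitude ratio within `magnitude_ratio_bounds`, at least
#' `min_agreeing_neighbors` of the <= 8 grid neighbors agreeing) removes
#' noise vectors that pass the fitting criteria.
#'
#' @param roi_size,roi_shift spatial window size and stride, px.
#' @param toi_length,toi_shift temporal window size and stride, frames.
#' @param max_tau largest time lag fitted, frames.
#' @param tau_min smallest time lag used in the velocity fit.
#' @param pixel_size um per px.
#' @param frame_interval s per frame.
#' @param immobile_modes_removed temporal frequencies zeroed per pixel.
#' @param min_fit_r2 minimum lag-regression R^2 for a valid vector.
#' @param intercept fit the lag regression with a free intercept.
#' @param normalize_correlation divide correlations by the mean-product
#'   normalization (peak positions are unaffected).
#' @param search_pad px; when > 0 the lagged frame of each correlation is
#'   taken from the ROI grown by this margin (cut from the full frame), so
#'   structure leaving the ROI stays visible and the window-truncation
#'   bias on peak positions is removed; measurable lags are then capped at
#'   `search_pad`.
#' @param similarity list with `max_angle_deg`, `magnitude_ratio_bounds`,
#'   `min_agreeing_neighbors`.
#' @return A `stics_config` object.
#' @export
stics_config <- function(roi_size = 16, roi_shift = 4, toi_length = 10,
                         toi_shift = 1, max_tau = 10, tau_min = 1,
                         pixel_size = 0.04, frame_interval = 15,
                         immobile_modes_removed = 1, min_fit_r2 = 0.9,
                         intercept = TRUE, normalize_correlation = TRUE,
                         search_pad = 0,
                         similarity = list(max_angle_deg = 45,
                                           magnitude_ratio_bounds = c(0.5, 2),
                                           min_agreeing_neighbors = 3)) {
  stopifnot(roi_size >= 4, roi_shift >= 1, roi_shift <= roi_size,
            toi_length >= 2, toi_shift >= 1, toi_shift <= toi_length,
            pixel_size > 0, frame_interval > 0,
            immobile_modes_removed >= 0, tau_min >= 0)
  max_tau <- min(max_tau, toi_length - 1)
  stopifnot(max_tau >= 1, tau_min < max_tau)
  structure(list(
    roi_size = as.integer(roi_size), roi_shift = as.integer(roi_shift),
    toi_length = as.integer(toi_length), toi_shift = as.integer(toi_shift),
    max_tau = as.integer(max_tau), tau_min = as.integer(tau_min),
    pixel_size = pixel_size, frame_interval = frame_interval,
    immobile_modes_removed = as.integer(immobile_modes_removed),
    min_fit_r2 = min_fit_r2, intercept = isTRUE(intercept),
    normalize_correlation = isTRUE(normalize_correlation),
    search_pad = as.integer(search_pad),
    similarity = similarity
  ), class = "stics_config")
}

#' Fourier immobile filter
#'
#' Per-pixel temporal discrete Fourier transform with the `modes` lowest
#' non-negative frequencies zeroed (1 = DC only, equivalent to subtracting
#' each pixel's temporal mean), then inverse transformed. Removes static
#' structure before correlation.
#'
#' @param series an [image_series()] or a (T, Y, X) array.
#' @param modes number of lowest frequencies removed; must satisfy
#'   `modes < n_frames / 2`.
#' @return Filtered object of the same type (real-valued).
#' @export
immobile_filter <- function(series, modes = 1) {
  if (inherits(series, "image_series")) {
    d <- dim(series$data)
    out <- series
    for (z in seq_len(d[2])) for (ci in seq_len(d[3])) {
      arr <- array(series$data[, z, ci, , , drop = FALSE], dim = d[c(1, 4, 5)])
      out$data[, z, ci, , ] <- immobile_filter(arr, modes)
    }
    return(out)
  }
  d <- dim(series)
  stopifnot(length(d) == 3)
  nt <- d[1]
  if (nt < 2) stop("immobile filter needs at least 2 frames")
  if (modes >= nt / 2) {
    stop(sprintf("modes = %d would remove all resolvable frequencies (n_frames = %d)",
                 modes, nt))
  }
  if (modes == 0) return(series)
  x <- matrix(series, nrow = nt)
  f <- mvfft(x)
  f[1, ] <- 0
  if (modes > 1) {
    for (j in seq_len(modes - 1)) {
      f[j + 1, ] <- 0
      f[nt + 1 - j, ] <- 0
    }
  }
  array(Re(mvfft(f, inverse = TRUE)) / nt, dim = d)
}

#' Enumerate ROI/TOI tiles
#'
#' All spatial windows with 0-based origins at multiples of `roi_shift`
#' such that the `roi_size` window fits, crossed with all temporal windows
#' at multiples of `toi_shift`, in deterministic row-major order (x fastest,
#' then y, then TOI).
#'
#' @param ny,nx,nt image height, width (px) and frame count.
#' @param config a [stics_config()].
#' @return `list(spatial = data.frame(x0, y0), toi_starts, tiles)` where
#'   `tiles` is the full (x0, y0, t0) enumeration (all 0-based).
#' @export
tile_roi_toi <- function(ny, nx, nt, config) {
  stopifnot(inherits(config, "stics_config"))
  if (nx < config$roi_size || ny < config$roi_size) {
    stop("image smaller than one ROI")
  }
  if (nt < config$toi_length) stop("series shorter than one TOI")
  x0 <- seq(0L, nx - config$roi_size, by = config$roi_shift)
  y0 <- seq(0L, ny - config$roi_size, by = config$roi_shift)
  t0 <- seq(0L, nt - config$toi_length, by = config$toi_shift)
  spatial <- expand.grid(x0 = x0, y0 = y0, KEEP.OUT.ATTRS = FALSE)
  tiles <- expand.grid(x0 = x0, y0 = y0, t0 = t0, KEEP.OUT.ATTRS = FALSE)
  list(spatial = spatial, toi_starts = t0, tiles = tiles)
}

fftshift_axis <- function(n) {
  # shift coordinates along one axis after fftshift reordering
  (-floor(n / 2)):(ceiling(n / 2) - 1)
}

fftshift2 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  m[c((floor(ny / 2) + 1):ny, 1:floor(ny / 2)),
    c((floor(nx / 2) + 1):nx, 1:floor(nx / 2))]
}

#' Space-time correlation function of one ROI/TOI window
#'
#' For each lag tau, the spatial cross-correlation of mean-subtracted
#' frame pairs (t, t + tau) is computed by FFT (circular), optionally
#' normalized by the mean-product convention
#' `<dI(t) dI(t+tau)> / (<I>_t <I>_{t+tau})`, and averaged over all pairs
#' within the window. When per-frame spatial means are not positive (as
#' after immobile filtering) the normalization constants fall back to 1;
#' peak positions, the quantity used downstream, are unaffected by the
#' convention.
#'
#' @param win numeric (T, Y, X) array (one ROI/TOI window).
#' @param max_tau largest lag; must satisfy `max_tau < T`.
#' @param normalize use the mean-product normalization.
#' @param search optional (T, Y + 2s, X + 2s) array containing the same
#'   window grown by `search_pad` pixels on every side (cut from the full
#'   frame). When supplied, the lagged frame is taken from this larger
#'   region, so structure that moves out of the ROI stays visible and the
#'   windowing bias on the peak position is removed; lags are then
#'   restricted to `|xi|, |eta| <= search_pad`.
#' @param search_pad the growth `s` of the search region, px.
#' @return A `stics_corr`: `values` (xi x eta x tau+1 array, lag axes
#'   centered by `fftshift`), `xi`, `eta` (px), `max_tau`.
#' @export
spacetime_correlation <- function(win, max_tau, normalize = TRUE,
                                  search = NULL, search_pad = 0) {
  d <- dim(win)
  stopifnot(length(d) == 3)
  nt <- d[1]; ny <- d[2]; nx <- d[3]
  if (max_tau >= nt) stop("max_tau must be smaller than the TOI length")
  if (any(!is.finite(win))) stop("window contains non-finite values")
  use_search <- !is.null(search) && search_pad > 0
  if (use_search) {
    ds <- dim(search)
    stopifnot(length(ds) == 3, ds[1] == nt,
              ds[2] == ny + 2 * search_pad, ds[3] == nx + 2 * search_pad)
  }
  py <- if (use_search) ny + 2 * search_pad else ny
  px <- if (use_search) nx + 2 * search_pad else nx
  mus <- numeric(nt)
  ffts_a <- vector("list", nt)
  ffts_b <- vector("list", nt)
  for (t in seq_len(nt)) {
    fr <- matrix(win[t, , ], ny, nx)
    mus[t] <- mean(fr)
    a <- matrix(0, py, px)
    a[(1:ny) + if (use_search) search_pad else 0L,
      (1:nx) + if (use_search) search_pad else 0L] <- fr - mus[t]
    ffts_a[[t]] <- fft(a)
    if (use_search) {
      sb <- matrix(search[t, , ], py, px)
      ffts_b[[t]] <- fft(sb - mean(sb))
    }
  }
  if (!use_search) ffts_b <- ffts_a
  npix <- ny * nx
  vals <- NULL
  for (tau in 0:max_tau) {
    acc <- matrix(0 + 0i, py, px)
    np <- nt - tau
    for (t in seq_len(np)) {
      w <- 1
      if (normalize) {
        mprod <- mus[t] * mus[t + tau]
        if (is.finite(mprod) && mprod > 0) w <- 1 / mprod
      }
      acc <- acc + w * Conj(ffts_a[[t]]) * ffts_b[[t + tau]]
    }
    # proper inverse DFT plus the spatial average over the ROI
    g <- Re(fft(acc, inverse = TRUE)) / (py * px * npix)
    g <- fftshift2(g / np)
    if (use_search) {
      keep_y <- which(abs(fftshift_axis(py)) <= search_pad)
      keep_x <- which(abs(fftshift_axis(px)) <= search_pad)
      g <- g[keep_y, keep_x]
    }
    if (is.null(vals)) vals <- array(NA_real_, c(nrow(g), ncol(g), max_tau + 1))
    vals[, , tau + 1] <- g
  }
  structure(list(
    values = vals,
    eta = if (use_search) (-search_pad):search_pad else fftshift_axis(ny),
    xi = if (use_search) (-search_pad):search_pad else fftshift_axis(nx),
    max_tau = as.integer(max_tau)
  ), class = "stics_corr")
}

# Fast 2D elliptical Gaussian + offset fit of a correlation surface around
# its discrete argmax. Returns sub-pixel peak center in lag units.
fit_gaussian2d_peak <- function(surface, xi, eta, crop_halfwidth = 3) {
  ny <- nrow(surface); nx <- ncol(surface)
  im <- which.max(surface)
  iy <- (im - 1) %% ny + 1
  ix <- (im - 1) %/% ny + 1
  if (iy == 1 || iy == ny || ix == 1 || ix == nx) {
    return(list(xi_hat = NA_real_, eta_hat = NA_real_,
                r_squared = NA_real_, valid = FALSE, reason = "peak on window edge"))
  }
  ys <- max(1, iy - crop_halfwidth):min(ny, iy + crop_halfwidth)
  xs <- max(1, ix - crop_halfwidth):min(nx, ix + crop_halfwidth)
  z <- surface[ys, xs]
  gx <- xi[xs]; gy <- eta[ys]
  X <- matrix(gx, length(gy), length(gx), byrow = TRUE)
  Y <- matrix(gy, length(gy), length(gx))
  zv <- as.vector(z); Xv <- as.vector(X); Yv <- as.vector(Y)
  p0 <- c(A = max(zv) - min(zv), x0 = xi[ix], y0 = eta[iy],
          sx = 1.5, sy = 1.5, c = min(zv))
  lower <- c(A = 0, x0 = min(gx), y0 = min(gy), sx = 0.3, sy = 0.3, c = -Inf)
  upper <- c(A = Inf, x0 = max(gx), y0 = max(gy),
             sx = nx, sy = ny, c = Inf)
  res_fn <- function(p) {
    p[[1]] * exp(-((Xv - p[[2]])^2 / (2 * p[[4]]^2) +
                     (Yv - p[[3]])^2 / (2 * p[[5]]^2))) + p[[6]] - zv
  }
  jac_fn <- function(p) {
    dx <- Xv - p[[2]]
    dy <- Yv - p[[3]]
    e <- exp(-(dx^2 / (2 * p[[4]]^2) + dy^2 / (2 * p[[5]]^2)))
    cbind(e,
          p[[1]] * e * dx / p[[4]]^2,
          p[[1]] * e * dy / p[[5]]^2,
          p[[1]] * e * dx^2 / p[[4]]^3,
          p[[1]] * e * dy^2 / p[[5]]^3,
          1)
  }
  fit <- tryCatch(
    suppressWarnings(nls.lm(par = p0, lower = lower, upper = upper,
                            fn = res_fn, jac = jac_fn,
                            control = nls.lm.control(maxiter = 150))),
    error = function(e) e)
  if (inherits(fit, "error") || fit$info %in% c(0, 9)) {
    return(list(xi_hat = NA_real_, eta_hat = NA_real_,
                r_squared = NA_real_, valid = FALSE, reason = "fit failed"))
  }
  p <- fit$par
  sst <- sum((zv - mean(zv))^2)
  r2 <- if (sst > 0) 1 - sum(res_fn(p)^2) / sst else NA_real_
  list(xi_hat = unname(p["x0"]), eta_hat = unname(p["y0"]),
       r_squared = r2, valid = TRUE, reason = NA_character_)
}

#' Sub-pixel correlation-peak position at one lag
#'
#' Seeds a 2D elliptical Gaussian (with offset) at the discrete argmax of
#' the lag-`tau` correlation plane and refines by least squares; peaks on
#' the window edge are flagged invalid.
#'
#' @param corr a [spacetime_correlation()] result.
#' @param tau time lag (0..max_tau).
#' @return `list(xi_hat, eta_hat, r_squared, valid, reason)` (px).
#' @export
fit_correlation_peak <- function(corr, tau) {
  stopifnot(inherits(corr, "stics_corr"), tau >= 0, tau <= corr$max_tau)
  surface <- corr$values[, , tau + 1]
  if (max(surface) - min(surface) <= 0) {
    return(list(xi_hat = NA_real_, eta_hat = NA_real_, r_squared = NA_real_,
                valid = FALSE, reason = "flat surface"))
  }
  fit_gaussian2d_peak(surface, corr$xi, corr$eta)
}

#' Velocity from the lag dependence of the correlation peak
#'
#' Least-squares line through the valid (tau, xi) and (tau, eta) peak
#' positions; the slope in px/frame is converted to um/min with
#' `v = slope * pixel_size * 60 / frame_interval`.
#'
#' @param peaks data.frame with columns `tau`, `xi`, `eta`, `valid`.
#' @param config a [stics_config()] (calibration, intercept choice).
#' @return `list(vx, vy, fit_r_squared, valid, n_lags)` (um/min).
#' @export
velocity_from_lags <- function(peaks, config) {
  ok <- peaks$valid & is.finite(peaks$xi) & is.finite(peaks$eta)
  if (sum(ok) < 3) {
    return(list(vx = NA_real_, vy = NA_real_, fit_r_squared = NA_real_,
                valid = FALSE, n_lags = sum(ok)))
  }
  tau <- peaks$tau[ok]
  fit1d <- function(yv) {
    if (config$intercept) {
      tm <- mean(tau); ym <- mean(yv)
      vt <- sum((tau - tm)^2)
      slope <- sum((tau - tm) * (yv - ym)) / vt
      res <- yv - ym - slope * (tau - tm)
      list(slope = slope, ssr = sum(res^2), sst = sum((yv - ym)^2))
    } else {
      slope <- sum(tau * yv) / sum(tau^2)
      res <- yv - slope * tau
      list(slope = slope, ssr = sum(res^2), sst = sum(yv^2))
    }
  }
  fx <- fit1d(peaks$xi[ok])
  fy <- fit1d(peaks$eta[ok])
  sst <- fx$sst + fy$sst
  r2 <- if (sst < 1e-12) 1 else 1 - (fx$ssr + fy$ssr) / sst
  scale <- config$pixel_size * 60 / config$frame_interval
  list(vx = fx$slope * scale, vy = fy$slope * scale,
       fit_r_squared = r2, valid = TRUE, n_lags = sum(ok))
}

#' Map a velocity vector field by twSTICS
#'
#' Runs the full chain on one channel of a time-lapse: immobile filtering,
#' ROI/TOI tiling, per-tile space-time correlation, Gaussian peak tracking
#' over lags `tau_min..max_tau`, velocity regression, the fit-quality
#' criterion (`fit_r_squared >= min_fit_r2`), and the neighbor-similarity
#' noise-vector filter.
#'
#' @param series an [image_series()] time-lapse (uses its calibration when
#'   the config's defaults were not overridden) or (T, Y, X) array.
#' @param config a [stics_config()].
#' @param channel,z plane selectors for image-series input.
#' @return A `vector_field` data.frame: one row per ROI/TOI with `x_um`,
#'   `y_um` (ROI center), `toi`, `ix`, `iy` (grid indices), `vx`, `vy`,
#'   `magnitude`, `direction` (um/min, rad), `fit_r_squared`, `valid`,
#'   `retained`. The config is attached as attribute `config`.
#' @export
stics_vector_field <- function(series, config, channel = 1, z = 1) {
  stopifnot(inherits(config, "stics_config"))
  frames <- if (inherits(series, "image_series")) {
    get_frames(series, channel, z)
  } else series
  d <- dim(frames)
  stopifnot(length(d) == 3)
  if (config$immobile_modes_removed > 0) {
    frames <- immobile_filter(frames, config$immobile_modes_removed)
  }
  tl <- tile_roi_toi(d[2], d[3], d[1], config)
  taus <- config$tau_min:config$max_tau
  rows <- vector("list", nrow(tl$tiles))
  half <- (config$roi_size - 1) / 2
  s <- config$search_pad
  for (i in seq_len(nrow(tl$tiles))) {
    x0 <- tl$tiles$x0[i]; y0 <- tl$tiles$y0[i]; t0 <- tl$tiles$t0[i]
    tsel <- (t0 + 1):(t0 + config$toi_length)
    win <- frames[tsel,
                  (y0 + 1):(y0 + config$roi_size),
                  (x0 + 1):(x0 + config$roi_size), drop = FALSE]
    search <- NULL
    if (s > 0) {
      # ROI grown by s on each side, zero-padded where it leaves the frame
      search <- array(0, c(config$toi_length, config$roi_size + 2 * s,
                           config$roi_size + 2 * s))
      ys <- (y0 + 1 - s):(y0 + config$roi_size + s)
      xs <- (x0 + 1 - s):(x0 + config$roi_size + s)
      ok_y <- ys >= 1 & ys <= d[2]
      ok_x <- xs >= 1 & xs <= d[3]
      search[, which(ok_y), which(ok_x)] <-
        frames[tsel, ys[ok_y], xs[ok_x], drop = FALSE]
    }
    corr <- spacetime_correlation(win, config$max_tau,
                                  normalize = config$normalize_correlation,
                                  search = search, search_pad = s)
    pk <- lapply(taus, function(tau) fit_correlation_peak(corr, tau))
    peaks <- data.frame(
      tau = taus,
      xi = vapply(pk, `[[`, numeric(1), "xi_hat"),
      eta = vapply(pk, `[[`, numeric(1), "eta_hat"),
      valid = vapply(pk, `[[`, logical(1), "valid"))
    v <- velocity_from_lags(peaks, config)
    rows[[i]] <- data.frame(
      x_um = (x0 + half) * config$pixel_size,
      y_um = (y0 + half) * config$pixel_size,
      toi = match(t0, tl$toi_starts),
      ix = x0 %/% config$roi_shift,
      iy = y0 %/% config$roi_shift,
      vx = v$vx, vy = v$vy,
      fit_r_squared = v$fit_r_squared,
      valid = isTRUE(v$valid) && is.finite(v$fit_r_squared) &&
        v$fit_r_squared >= config$min_fit_r2)
  }
  field <- do.call(rbind, rows)
  field$magnitude <- sqrt(field$vx^2 + field$vy^2)
  field$direction <- atan2(field$vy, field$vx)
  field <- filter_noise_vectors(field, config$similarity)
  attr(field, "config") <- config
  class(field) <- c("vector_field", class(field))
  field
}
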