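# Podosome core detection: multi-scale Laplacian-of-Gaussian blob response
# with non-maximum suppression and sub-pixel quadratic refinement.

# Wrapped scale-normalized LoG kernel (sigma in px), sign-flipped so bright
# blobs give positive response; zero-mean so constant images respond 0.
log_kernel_wrapped <- function(ny, nx, sigma_px) {
  iy <- 0:(ny - 1); dy <- pmin(iy, ny - iy)
  ix <- 0:(nx - 1); dx <- pmin(ix, nx - ix)
  r2 <- outer(dy^2, dx^2, "+")
  g <- exp(-r2 / (2 * sigma_px^2))
  k <- -(r2 - 2 * sigma_px^2) / sigma_px^2 * g  # sigma^2 * -laplacian(G), unnormalized
  k <- k / sum(g)
  k - mean(k)
}

# Quadratic sub-pixel offset from a 1D triplet (v_minus, v_0, v_plus).
quad_offset <- function(vm, v0, vp) {
  den <- 2 * v0 - vm - vp
  off <- ifelse(abs(den) < .Machine$double.eps, 0, (vp - vm) / (2 * den))
  pmax(pmin(off, 0.5), -0.5)
}

#' Detect podosome core centers
#'
#' Multi-scale Laplacian-of-Gaussian blob detection on a single image plane.
#' Candidate scales are core diameters spanning `scale_range` (um); the blob
#' sigma for diameter d is d / (2 sqrt(2)). Local maxima of the per-pixel
#' maximum response across scales are suppressed to `min_separation`,
#' refined to sub-pixel position by a quadratic fit on the 3x3 response
#' neighborhood, and returned sorted by descending response (ties broken by
#' y then x). An externally supplied centers table can be passed anywhere a
#' `podosome_centers` object is accepted, which is the semi-automatic
#' escape hatch for manual seeding.
#'
#' @param image an [image_series()] or matrix.
#' @param channel channel to detect on (the actin/core image).
#' @param scale_range core diameter range searched, um.
#' @param min_separation suppression radius between accepted peaks, um.
#' @param threshold_rel discard maxima weaker than this fraction of the
#'   strongest response.
#' @param n_scales number of log-spaced scales in `scale_range`.
#' @param t,z frame / plane selectors.
#' @param pixel_size required when `image` is a bare matrix.
#' @return A `podosome_centers` object: `coordinates` (data.frame with
#'   `x_um`, `y_um`, `response`, `detection_scale_um`), `source_channel`.
#' @export
detect_cores <- function(image, channel = 1, scale_range = c(0.5, 0.7),
                         min_separation = 0.5, threshold_rel = 0.2,
                         n_scales = 5, t = 1, z = 1, pixel_size = NULL) {
  if (inherits(image, "image_series")) {
    m <- get_plane(image, channel, t, z)
    px <- image$pixel_size
  } else {
    m <- as.matrix(image)
    px <- pixel_size
    if (is.null(px)) stop("pixel_size required for matrix input")
  }
  if (any(!is.finite(m))) stop("image contains non-finite pixels")
  ny <- nrow(m); nx <- ncol(m)
  stopifnot(length(scale_range) == 2, all(scale_range > 0),
            scale_range[1] <= scale_range[2])

  diameters <- exp(seq(log(scale_range[1]), log(scale_range[2]),
                       length.out = n_scales))
  sigmas_px <- diameters / (2 * sqrt(2)) / px
  fm <- fft(m)
  best <- matrix(-Inf, ny, nx)
  best_scale <- matrix(diameters[1], ny, nx)
  for (k in seq_along(sigmas_px)) {
    resp <- Re(fft(fm * fft(log_kernel_wrapped(ny, nx, sigmas_px[k])),
                   inverse = TRUE)) / (ny * nx)
    upd <- resp > best
    best[upd] <- resp[upd]
    best_scale[upd] <- diameters[k]
  }

  # strict 8-neighborhood local maxima (interior pixels only)
  iy <- 2:(ny - 1); ix <- 2:(nx - 1)
  c0 <- best[iy, ix]
  is_max <- c0 > best[iy - 1, ix] & c0 > best[iy + 1, ix] &
    c0 > best[iy, ix - 1] & c0 > best[iy, ix + 1] &
    c0 > best[iy - 1, ix - 1] & c0 > best[iy - 1, ix + 1] &
    c0 > best[iy + 1, ix - 1] & c0 > best[iy + 1, ix + 1] & c0 > 0
  # numeric-noise floor: a constant (or nearly constant) image has no blobs
  if (max(best) <= 1e-8 * max(abs(m), 1)) {
    is_max[] <- FALSE
  }
  hits <- which(is_max, arr.ind = TRUE)
  empty <- podosome_centers(data.frame(x_um = numeric(0), y_um = numeric(0),
                                       response = numeric(0),
                                       detection_scale_um = numeric(0)),
                            source_channel = channel)
  if (nrow(hits) == 0) return(empty)
  ry <- hits[, 1] + 1L  # back to full-image indices
  rx <- hits[, 2] + 1L
  resp <- best[cbind(ry, rx)]
  keep <- resp >= threshold_rel * max(resp)
  ry <- ry[keep]; rx <- rx[keep]; resp <- resp[keep]
  if (length(resp) == 0) return(empty)

  # deterministic order: descending response, ties by y then x (0-based)
  o <- order(-resp, ry, rx)
  ry <- ry[o]; rx <- rx[o]; resp <- resp[o]

  # greedy non-maximum suppression at min_separation
  min_sep_px2 <- (min_separation / px)^2
  kept <- integer(0)
  for (i in seq_along(resp)) {
    if (length(kept) == 0 ||
        min((ry[kept] - ry[i])^2 + (rx[kept] - rx[i])^2) >= min_sep_px2) {
      kept <- c(kept, i)
    }
  }
  ry <- ry[kept]; rx <- rx[kept]; resp <- resp[kept]

  dx <- quad_offset(best[cbind(ry, rx - 1L)], resp, best[cbind(ry, rx + 1L)])
  dy <- quad_offset(best[cbind(ry - 1L, rx)], resp, best[cbind(ry + 1L, rx)])
  podosome_centers(data.frame(
    x_um = (rx - 1 + dx) * px,
    y_um = (ry - 1 + dy) * px,
    response = resp,
    detection_scale_um = best_scale[cbind(ry, rx)]
  ), source_channel = channel)
}

#' Podosome center table
#'
#' @param coordinates data.frame with at least `x_um`, `y_um` (sub-pixel
#'   positions in um).
#' @param source_channel channel the centers were derived from.
#' @return A `podosome_centers` object.
#' @export
podosome_centers <- function(coordinates, source_channel = NA) {
  stopifnot(is.data.frame(coordinates),
            all(c("x_um", "y_um") %in% names(coordinates)))
  structure(list(coordinates = coordinates, source_channel = source_channel),
            class = "podosome_centers")
}

#' @export
print.podosome_centers <- function(x, ...) {
  cat(sprintf("<podosome_centers> %d centers (channel: %s)\n",
              nrow(x$coordinates), as.character(x$source_channel)))
  invisible(x)
}
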