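#' Calibrated n-dimensional image series
#'
#' The common data currency of the pipeline: a 5D intensity array with axes
#' (T, Z, C, Y, X) and physical calibration. 2D, 3D and time-lapse data are
#' stored with singleton axes so every stage sees the same layout.
#'
#' @param data numeric array; 2D `(Y, X)`, or any array already shaped
#'   `(T, Z, C, Y, X)`.
#' @param pixel_size lateral pixel size in um (> 0).
#' @param z_step z-plane spacing in um (`NA` for single-plane data).
#' @param frame_interval time between frames in s (`NA` for still images).
#' @param channels character vector of channel names (length = C axis).
#' @return An object of class `image_series`.
#' @export
image_series <- function(data, pixel_size, z_step = NA_real_,
                         frame_interval = NA_real_, channels = NULL) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || !is.finite(pixel_size) ||
      pixel_size <= 0) {
    stop("pixel_size must be a single positive number (um)")
  }
  d <- dim(data)
  if (is.null(d)) stop("data must be a matrix or array")
  if (length(d) == 2) {
    data <- array(data, dim = c(1, 1, 1, d[1], d[2]))
  } else if (length(d) != 5) {
    stop("data must be 2D (Y, X) or 5D (T, Z, C, Y, X)")
  }
  dim(data) <- unname(dim(data))
  d <- dim(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[3]))
  if (length(channels) != d[3]) stop("channels length must equal the C axis")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  structure(list(
    data = data,
    pixel_size = pixel_size,
    z_step = z_step,
    frame_interval = frame_interval,
    channels = channels
  ), class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_series> T=%d Z=%d C=%d Y=%d X=%d | %.3f um/px",
              d[1], d[2], d[3], d[4], d[5], x$pixel_size))
  if (!is.na(x$z_step)) cat(sprintf(" | z-step %.3f um", x$z_step))
  if (!is.na(x$frame_interval)) cat(sprintf(" | %.1f s/frame", x$frame_interval))
  cat("\n  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

n_frames <- function(img) dim(img$data)[1]
n_planes <- function(img) dim(img$data)[2]

channel_index <- function(img, channel) {
  if (is.numeric(channel)) {
    ci <- as.integer(channel)
    if (ci < 1 || ci > length(img$channels)) stop("channel index out of range")
    return(ci)
  }
  ci <- match(channel, img$channels)
  if (is.na(ci)) stop(sprintf("channel '%s' not found (have: %s)", channel,
                              paste(img$channels, collapse = ", ")))
  ci
}

#' Extract a single 2D plane
#'
#' @param img an [image_series()].
#' @param channel channel name or index.
#' @param t,z frame and z-plane indices (1-based).
#' @return A numeric `(Y, X)` matrix.
#' @export
get_plane <- function(img, channel = 1, t = 1, z = 1) {
  d <- dim(img$data)
  if (t < 1 || t > d[1] || z < 1 || z > d[2]) stop("t or z out of range")
  img$data[t, z, channel_index(img, channel), , ]
}

# Frames of one channel at one z as an array (T, Y, X).
get_frames <- function(img, channel = 1, z = 1) {
  ci <- channel_index(img, channel)
  d <- dim(img$data)
  arr <- img$data[, z, ci, , , drop = FALSE]
  array(arr, dim = c(d[1], d[4], d[5]))
}
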