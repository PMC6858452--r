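# Readers and writers: multi-page TIFF image series with a JSON calibration
# sidecar, vector-field / profile CSV tables, and run configurations.

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image series to TIFF
#'
#' Pages are written in (T, Z, C) order as 32-bit float TIFF; axis lengths
#' and physical calibration (pixel size, z-step, frame interval, channel
#' names, intensity scale) go to a JSON sidecar next to the file, since the
#' plain TIFF container carries no reliable calibration tags.
#'
#' @param img an [image_series()].
#' @param path output `.tif` path (sidecar written to `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_image_series <- function(img, path) {
  stopifnot(inherits(img, "image_series"))
  d <- dim(img$data)
  offset <- min(img$data)
  scale <- max(max(img$data) - offset, 1e-12)
  pages <- list()
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ci in seq_len(d[3])) {
    pages[[length(pages) + 1]] <- (img$data[t, z, ci, , ] - offset) / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(
    axes = "TZCYX",
    shape = as.integer(d),
    pixel_size_um = img$pixel_size,
    z_step_um = img$z_step,
    frame_interval_s = img$frame_interval,
    channels = img$channels,
    intensity_scale = scale,
    intensity_offset = offset
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read an image series from TIFF
#'
#' Reads a multi-page TIFF written by [write_image_series()] (or any plain
#' TIFF) and restores the (T, Z, C, Y, X) layout from the JSON sidecar if
#' present; otherwise all pages are stacked on Z with singleton T and C.
#' Calibration must come from the sidecar or the overrides; missing pixel
#' size is an error.
#'
#' @param path `.tif` path.
#' @param pixel_size,z_step,frame_interval calibration overrides (um, um, s).
#' @return An [image_series()].
#' @export
read_image_series <- function(path, pixel_size = NULL, z_step = NULL,
                              frame_interval = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  px <- pixel_size %||% meta$pixel_size_um
  if (is.null(px) || is.na(px)) {
    stop("no pixel size: provide a calibration override or a sidecar JSON")
  }
  zs <- z_step %||% meta$z_step_um %||% NA_real_
  fi <- frame_interval %||% meta$frame_interval_s %||% NA_real_
  if (!is.null(meta) && identical(meta$axes, "TZCYX")) {
    d <- meta$shape
    arr <- array(0, dim = d)
    k <- 0
    for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ci in seq_len(d[3])) {
      k <- k + 1
      arr[t, z, ci, , ] <- pages[[k]] * meta$intensity_scale +
        (meta$intensity_offset %||% 0)
    }
    chans <- meta$channels
  } else {
    ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
    arr <- array(0, dim = c(1, length(pages), 1, ny, nx))
    for (z in seq_along(pages)) {
      pg <- pages[[z]]
      if (length(dim(pg)) == 3) pg <- pg[, , 1]  # drop extra samples
      arr[1, z, 1, , ] <- pg
    }
    chans <- NULL
  }
  image_series(arr, pixel_size = as.numeric(px), z_step = as.numeric(zs),
               frame_interval = as.numeric(fi), channels = chans)
}

#' Write a vector field as CSV
#'
#' Columns carry units in their names; the attached config is serialized to
#' a JSON sidecar so a run can be reproduced exactly.
#'
#' @param field a `vector_field`.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_vector_field <- function(field, path) {
  out <- data.frame(
    x_um = field$x_um, y_um = field$y_um, t_index = field$toi,
    vx_um_min = field$vx, vy_um_min = field$vy,
    magnitude_um_min = field$magnitude, direction_rad = field$direction,
    r2 = field$fit_r_squared, retained = field$retained
  )
  write.csv(out, path, row.names = FALSE)
  cfg <- attr(field, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Write a PVC surface as CSV
#'
#' One row per (separation bin, temporal lag) cell.
#'
#' @param result a [pair_vector_correlation()] result.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_pvc <- function(result, path) {
  g <- expand.grid(dr_center_um = result$dr_bin_centers,
                   dt_lag = result$dt_lags)
  g$dt_min <- g$dt_lag * result$toi_step_min
  g$pvc <- as.vector(result$pvc_values)
  g$m_pairs <- as.vector(result$m_pairs)
  write.csv(g, path, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' A serializable bundle of input paths, channel mapping, calibration
#' overrides, module parameter blocks, seed and output directory;
#' `load_run_config(save_run_config(c))` round-trips exactly.
#'
#' @param input_paths character vector of input files.
#' @param channel_map named list mapping channel names to indices.
#' @param calibration list with any of `pixel_size_um`, `z_step_um`,
#'   `frame_interval_s` (all positive).
#' @param params named list of module parameter blocks.
#' @param seed integer seed.
#' @param output_dir output directory.
#' @return A `run_config` object.
#' @export
run_config <- function(input_paths = character(), channel_map = list(),
                       calibration = list(), params = list(), seed = 1L,
                       output_dir = ".") {
  cal <- calibration
  for (f in names(cal)) {
    if (!is.null(cal[[f]]) && !is.na(cal[[f]]) && cal[[f]] <= 0) {
      stop(sprintf("calibration field %s must be positive", f))
    }
  }
  if (anyDuplicated(names(channel_map))) stop("channel names must be unique")
  structure(list(
    input_paths = input_paths, channel_map = channel_map,
    calibration = calibration, params = params, seed = as.integer(seed),
    output_dir = output_dir
  ), class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(input_paths = as.character(x$input_paths),
             channel_map = as.list(x$channel_map),
             calibration = as.list(x$calibration),
             params = as.list(x$params),
             seed = x$seed, output_dir = x$output_dir)
}

#' Serialize ground truth
#'
#' Writes the scalar ground-truth fields (true FWHM, ring diameter,
#' z-heights, ...) as JSON and the centers table as CSV next to it.
#'
#' @param truth a `ground_truth` from a `simulate_*()` call.
#' @param path base path; writes `<path>.json` and `<path>_centers.csv`.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  flat <- Filter(function(x) !is.data.frame(x) && !is.matrix(x),
                 unclass(truth))
  jsonlite::write_json(flat, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  if (!is.null(truth$centers)) {
    write.csv(truth$centers, paste0(path, "_centers.csv"), row.names = FALSE)
  }
  invisible(path)
}
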