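# Radiating-filament length measurement: background suppression, hysteresis
# thresholding, morphological skeletonization and geodesic branch tracing.

# 8-connected component labels of a logical matrix (BFS; skeletons are
# sparse so this is cheap).
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  ny <- nrow(mask); nx <- ncol(mask)
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      py <- (p - 1L) %% ny + 1L
      px <- (p - 1L) %/% ny + 1L
      for (dy in -1:1) for (dx in -1:1) {
        qy <- py + dy; qx <- px + dx
        if (qy < 1 || qy > ny || qx < 1 || qx > nx) next
        q <- (qx - 1L) * ny + qy
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Hysteresis threshold: keep weak-mask components that contain at least one
# strong pixel.
hysteresis_threshold <- function(mat, low, high) {
  weak <- mat >= low
  strong <- mat >= high
  if (!any(strong)) return(matrix(FALSE, nrow(mat), ncol(mat)))
  lab <- label_components8(weak)
  keep <- unique(lab[strong])
  keep <- keep[keep != 0L]
  lab %in% keep & weak
}

# Zhang-Suen thinning of a logical mask to a 1-px-wide 8-connected skeleton.
skeletonize <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.integer(mask)
  ny <- nrow(m); nx <- ncol(m)
  iy <- 2:(ny - 1); ix <- 2:(nx - 1)
  shift <- function(dy, dx) m[iy + dy, ix + dx]
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shift(-1, 0); p3 <- shift(-1, 1); p4 <- shift(0, 1)
      p5 <- shift(1, 1);  p6 <- shift(1, 0);  p7 <- shift(1, -1)
      p8 <- shift(0, -1); p9 <- shift(-1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m[iy, ix] == 1L & b >= 2 & b <= 6 & a == 1
      cond <- cond & if (pass == 1) {
        (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        sub <- m[iy, ix]
        sub[cond] <- 0L
        m[iy, ix] <- sub
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(ny - 1), 2:(nx - 1)] == 1L
}

# Count of 8-neighbors for every skeleton pixel.
neighbor_count <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.integer(mask)
  iy <- 2:(nrow(m) - 1); ix <- 2:(ncol(m) - 1)
  (m[iy - 1, ix - 1] + m[iy - 1, ix] + m[iy - 1, ix + 1] +
     m[iy, ix - 1] + m[iy, ix + 1] +
     m[iy + 1, ix - 1] + m[iy + 1, ix] + m[iy + 1, ix + 1])
}

# Walk a skeleton path starting at an endpoint; returns the visited pixel
# coordinates (rows of [y, x]) in order. Stops at junctions (pixels with
# more than 2 neighbors), other endpoints, or when `stop_at(y, x)` is TRUE.
trace_from <- function(skel, nbr, y0, x0, stop_at = NULL) {
  ny <- nrow(skel); nx <- ncol(skel)
  path <- matrix(c(y0, x0), 1, 2)
  visited <- matrix(FALSE, ny, nx)
  visited[y0, x0] <- TRUE
  cy <- y0; cx <- x0
  repeat {
    if (!is.null(stop_at) && stop_at(cy, cx)) break
    cand <- NULL
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      qy <- cy + dy; qx <- cx + dx
      if (qy < 1 || qy > ny || qx < 1 || qx > nx) next
      if (skel[qy, qx] && !visited[qy, qx]) cand <- rbind(cand, c(qy, qx))
    }
    if (is.null(cand) || nrow(cand) != 1) break  # endpoint or junction
    cy <- cand[1, 1]; cx <- cand[1, 2]
    visited[cy, cx] <- TRUE
    path <- rbind(path, c(cy, cx))
    if (nbr[cy, cx] > 2) break  # entered a junction pixel
  }
  path
}

# Thinning erodes one to two pixels from rounded branch tips; recover them
# by stepping from the tip along the last path direction while still inside
# the pre-skeleton mask. Returns the extra length in px.
tip_extension_px <- function(mask, path) {
  n <- nrow(path)
  if (n < 2) return(0)
  dir <- path[n, ] - path[n - 1, ]
  if (all(dir == 0)) return(0)
  step <- sqrt(sum(dir^2))
  p <- path[n, ]
  extra <- 0
  repeat {
    q <- p + dir
    if (q[1] < 1 || q[1] > nrow(mask) || q[2] < 1 || q[2] > ncol(mask)) break
    if (!mask[q[1], q[2]]) break
    extra <- extra + step
    p <- q
  }
  extra
}

path_length_px <- function(path) {
  if (nrow(path) < 2) return(0)
  sum(sqrt(rowSums((path[-1, , drop = FALSE] -
                      path[-nrow(path), , drop = FALSE])^2)))
}

#' Measure radiating filament lengths
#'
#' Filament channel processing: white top-hat background suppression,
#' hysteresis thresholding, skeletonization, then tracing of each skeleton
#' branch from its tip. A branch is a radiating filament when the traced
#' path reaches within `core_radius` of a podosome center; its length is
#' the geodesic path length (um) from the core boundary to the tip. With
#' `centers = NULL` the lengths of all skeleton branches (tip to tip or
#' junction) are returned, which is useful for calibration on drawn
#' segments.
#'
#' @param image an [image_series()] or matrix (filament channel).
#' @param centers podosome centers (`podosome_centers`, matrix, or NULL).
#' @param channel,t,z plane selectors.
#' @param core_radius radius of the core neighborhood, um.
#' @param tophat_radius structuring-disc radius for top-hat filtering, um.
#' @param low_fraction,high_fraction hysteresis thresholds as fractions of
#'   the maximum top-hat response.
#' @param pixel_size required for matrix input.
#' @return Numeric vector of filament lengths in um.
#' @export
filament_lengths <- function(image, centers = NULL, channel = 1,
                             t = 1, z = 1, core_radius = 0.25,
                             tophat_radius = 0.3, low_fraction = 0.1,
                             high_fraction = 0.5, pixel_size = NULL) {
  if (inherits(image, "image_series")) {
    m <- get_plane(image, channel, t, z)
    px <- image$pixel_size
  } else {
    m <- as.matrix(image)
    px <- pixel_size
    if (is.null(px)) stop("pixel_size required for matrix input")
  }
  brush_size <- 2 * round(tophat_radius / px) + 1
  th <- if (brush_size >= 3) {
    EBImage::whiteTopHat(m, EBImage::makeBrush(brush_size, shape = "disc"))
  } else {
    m - min(m)
  }
  peak <- max(th)
  if (peak <= 0) return(numeric(0))
  mask <- hysteresis_threshold(th, low_fraction * peak, high_fraction * peak)
  if (!any(mask)) return(numeric(0))
  # tips are extended only through the strong (half-max) mask, so measured
  # endpoints follow the FWHM convention for object boundaries
  strong <- th >= high_fraction * peak
  skel <- skeletonize(mask)
  nbr <- neighbor_count(skel)
  ends <- which(skel & nbr == 1, arr.ind = TRUE)
  if (nrow(ends) == 0) return(numeric(0))

  pts <- if (!is.null(centers)) center_coords(centers) else NULL
  near_core <- function(y, x) {
    if (is.null(pts)) return(FALSE)
    xu <- (x - 1) * px; yu <- (y - 1) * px
    any((pts[, 1] - xu)^2 + (pts[, 2] - yu)^2 <= core_radius^2)
  }

  lengths <- numeric(0)
  for (i in seq_len(nrow(ends))) {
    y0 <- ends[i, 1]; x0 <- ends[i, 2]
    if (is.null(pts)) {
      path <- trace_from(skel, nbr, y0, x0)
      # each tip-to-tip branch would be reported twice; keep the tip with
      # the smaller linear index
      other <- path[nrow(path), ]
      if (nbr[other[1], other[2]] == 1 &&
          ((other[2] - 1) * nrow(skel) + other[1]) <
            ((x0 - 1) * nrow(skel) + y0)) next
      ext <- tip_extension_px(strong, path) +
        tip_extension_px(strong, path[rev(seq_len(nrow(path))), , drop = FALSE])
      lengths <- c(lengths, (path_length_px(path) + ext) * px)
    } else {
      if (near_core(y0, x0)) next  # trace from the distal tip only
      path <- trace_from(skel, nbr, y0, x0, stop_at = near_core)
      tipend <- path[nrow(path), ]
      if (!near_core(tipend[1], tipend[2])) next  # never reached a core
      # drop the final in-core pixel so the length runs tip -> core boundary
      if (nrow(path) > 1) path <- path[-nrow(path), , drop = FALSE]
      # the walk started at the (eroded) distal tip: restore the tip end
      ext <- tip_extension_px(strong, path[rev(seq_len(nrow(path))), ,
                                           drop = FALSE])
      lengths <- c(lengths, (path_length_px(path) + ext) * px)
    }
  }
  lengths
}
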