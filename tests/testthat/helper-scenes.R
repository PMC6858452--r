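# Shared fixture builders (everything is generated in code at test time).

# Small, quickly rendered cluster scene.
small_scene <- function(n = 6, seed = 42, ...) {
  scene_spec(field_size = c(6, 6), n_podosomes = n, min_separation = 1.2,
             margin = 0.8, seed = seed, ...)
}

# Render a single noiseless podosome (core + ring) for symmetry oracles.
single_podosome_image <- function(core_sigma = 0.17, ring_radius = 0.385,
                                  psf_sigma = 0, background = 0) {
  sp <- scene_spec(field_size = c(4, 4), n_podosomes = 0,
                   core_sigma = core_sigma, ring_radius = ring_radius,
                   psf_sigma = psf_sigma, background = background,
                   read_noise_sigma = 0, seed = 1)
  g <- podopipe:::scene_grid(sp)
  ctr <- matrix(c(2, 2), 1, 2)
  core <- podopipe:::render_spots(g["ny"], g["nx"], sp$pixel_size, ctr, 100,
                                  core_sigma)
  ring <- podopipe:::render_spots(g["ny"], g["nx"], sp$pixel_size, ctr, 100,
                                  sp$ring_sigma, ring_radius = ring_radius)
  arr <- array(0, dim = c(1, 1, 2, g["ny"], g["nx"]))
  arr[1, 1, 1, , ] <- core + background
  arr[1, 1, 2, , ] <- ring + background
  list(image = image_series(arr, sp$pixel_size, channels = c("core", "ring")),
       center = c(2, 2), spec = sp)
}

# Brute-force space-time correlation (direct double loop over lags).
brute_spacetime_correlation <- function(win, max_tau, normalize = TRUE) {
  nt <- dim(win)[1]; ny <- dim(win)[2]; nx <- dim(win)[3]
  xi <- (-floor(nx / 2)):(ceiling(nx / 2) - 1)
  eta <- (-floor(ny / 2)):(ceiling(ny / 2) - 1)
  out <- array(0, c(ny, nx, max_tau + 1))
  for (tau in 0:max_tau) {
    np <- nt - tau
    acc <- matrix(0, ny, nx)
    for (t in seq_len(np)) {
      f1 <- matrix(win[t, , ], ny, nx)
      f2 <- matrix(win[t + tau, , ], ny, nx)
      m1 <- mean(f1); m2 <- mean(f2)
      d1 <- f1 - m1; d2 <- f2 - m2
      g <- matrix(0, ny, nx)
      for (ie in seq_along(eta)) for (ix in seq_along(xi)) {
        ys <- ((0:(ny - 1)) + eta[ie]) %% ny + 1
        xs <- ((0:(nx - 1)) + xi[ix]) %% nx + 1
        g[ie, ix] <- sum(d1 * d2[ys, xs]) / (ny * nx)
      }
      w <- if (normalize && m1 * m2 > 0) 1 / (m1 * m2) else 1
      acc <- acc + w * g
    }
    out[, , tau + 1] <- acc / np
  }
  out
}

# Brute-force PVC accumulation (explicit double loop over vector pairs).
brute_pvc <- function(v, dr_bin_width, max_dr, max_dt, normalize = FALSE) {
  n_bins <- max(ceiling(max_dr / dr_bin_width), 1)
  sums <- matrix(0, n_bins, max_dt + 1)
  counts <- matrix(0, n_bins, max_dt + 1)
  vec <- cbind(v$vx, v$vy)
  if (normalize) {
    nr <- sqrt(rowSums(vec^2))
    vec[nr > 0, ] <- vec[nr > 0, ] / nr[nr > 0]
  }
  n <- nrow(v)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dr <- sqrt((v$x_um[i] - v$x_um[j])^2 + (v$y_um[i] - v$y_um[j])^2)
    dt <- abs(v$toi[i] - v$toi[j])
    if (dr > max_dr || dt > max_dt) next
    b <- min(floor(dr / dr_bin_width), n_bins - 1) + 1
    sums[b, dt + 1] <- sums[b, dt + 1] + sum(vec[i, ] * vec[j, ])
    counts[b, dt + 1] <- counts[b, dt + 1] + 1
  }
  list(pvc = ifelse(counts > 0, sums / counts, NA_real_), m_pairs = counts)
}

# Random vector field data.frame on a grid (for PVC / filter tests).
random_vector_field <- function(n, extent_um = 5, n_toi = 3,
                                speed = 0.05) {
  ang <- runif(n, 0, 2 * pi)
  data.frame(
    x_um = runif(n, 0, extent_um), y_um = runif(n, 0, extent_um),
    toi = sample.int(n_toi, n, replace = TRUE),
    vx = speed * cos(ang), vy = speed * sin(ang),
    retained = TRUE)
}
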