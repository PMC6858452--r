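# twSTICS: immobile filter, tiling, correlation, peak and velocity fits.

test_that("immobile filter removes static structure exactly", {
  withr::with_seed(1, {
    arr <- array(rep(matrix(runif(64), 8, 8), each = 12), c(12, 8, 8))
  })
  filt <- immobile_filter(arr, 1)
  expect_lt(max(abs(filt)), 1e-10)
})

test_that("single-mode filter equals per-pixel temporal mean subtraction", {
  withr::with_seed(2, arr <- array(rnorm(10 * 6 * 6), c(10, 6, 6)))
  filt <- immobile_filter(arr, 1)
  means <- apply(arr, c(2, 3), mean)
  oracle <- sweep(arr, c(2, 3), means)
  expect_lt(max(abs(filt - oracle)), 1e-9 * diff(range(arr)))
})

test_that("the highest resolvable temporal frequency passes unchanged", {
  nt <- 8
  sig <- cos(pi * (0:(nt - 1)))  # Nyquist oscillation
  arr <- array(0, c(nt, 4, 4))
  for (t in 1:nt) arr[t, , ] <- sig[t]
  filt <- immobile_filter(arr, 1)
  expect_equal(filt, arr, tolerance = 1e-9)
  expect_error(immobile_filter(arr, 4), "resolvable")
})

test_that("tiling enumerates the documented overlap pattern", {
  cfg <- stics_config()
  tl <- tile_roi_toi(16, 16, 12, cfg)
  expect_equal(nrow(tl$spatial), 1)
  tl2 <- tile_roi_toi(16, 24, 12, cfg)
  expect_equal(sort(unique(tl2$tiles$x0)), c(0, 4, 8))
  expect_equal(sort(unique(tl2$tiles$y0)), 0)
  # printed protocol arithmetic: 75% spatial / 90% temporal overlap,
  # 2.5-min TOIs
  spatial_overlap <- (cfg$roi_size - cfg$roi_shift) / cfg$roi_size
  temporal_overlap <- (cfg$toi_length - cfg$toi_shift) / cfg$toi_length
  expect_equal(spatial_overlap, 0.75)
  expect_equal(temporal_overlap, 0.9)
  expect_equal(cfg$toi_length * cfg$frame_interval / 60, 2.5)
})

test_that("correlation matches the direct-sum oracle on random windows", {
  withr::with_seed(3, {
    win <- array(runif(6 * 8 * 8, 1, 2), c(6, 8, 8))
  })
  for (nrm in c(TRUE, FALSE)) {
    co <- spacetime_correlation(win, 4, normalize = nrm)
    bf <- brute_spacetime_correlation(win, 4, normalize = nrm)
    expect_lt(max(abs(co$values - bf)) / max(abs(bf)), 1e-10)
  }
})

test_that("static patterns peak at zero lag; translated pairs at the shift", {
  blob <- outer(exp(-((0:15) - 8)^2 / 8), exp(-((0:15) - 8)^2 / 8))
  arr <- array(0, c(4, 16, 16))
  for (t in 1:4) arr[t, , ] <- blob
  co <- spacetime_correlation(arr, 2)
  for (tau in 0:2) {
    s <- co$values[, , tau + 1]
    am <- which(s == max(s), arr.ind = TRUE)
    expect_equal(co$xi[am[2]], 0)
    expect_equal(co$eta[am[1]], 0)
  }
  # value at tau=0, origin is the global maximum of the tau=0 plane
  s0 <- co$values[, , 1]
  expect_equal(max(s0), s0[which(co$eta == 0), which(co$xi == 0)])

  f2 <- matrix(0, 16, 16); f2[7:10, 7:10] <- 1
  f1 <- matrix(0, 16, 16); f1[7:10, 5:8] <- 1  # f2 is f1 shifted +2 in x
  pair <- array(0, c(2, 16, 16)); pair[1, , ] <- f1; pair[2, , ] <- f2
  cp <- spacetime_correlation(pair, 1, normalize = FALSE)
  s <- cp$values[, , 2]
  am <- which(s == max(s), arr.ind = TRUE)
  expect_equal(co$xi[am[2]], 2)
  expect_equal(co$eta[am[1]], 0)
})

test_that("search-window correlation matches the direct-sum oracle", {
  s <- 3
  withr::with_seed(13, {
    big <- array(runif(5 * (8 + 2 * s) * (8 + 2 * s), 1, 2),
                 c(5, 8 + 2 * s, 8 + 2 * s))
  })
  win <- big[, (s + 1):(s + 8), (s + 1):(s + 8)]
  co <- spacetime_correlation(win, 3, normalize = FALSE,
                              search = big, search_pad = s)
  expect_equal(dim(co$values)[1:2], c(2 * s + 1, 2 * s + 1))
  # oracle: plain linear correlation of the ROI against the shifted search
  # region, averaged over pixels and frame pairs
  for (tau in 0:3) {
    np <- 5 - tau
    for (eta in c(-s, 0, 2)) for (xi in c(-1, 0, s)) {
      acc <- 0
      for (t in seq_len(np)) {
        a <- win[t, , ] - mean(win[t, , ])
        b <- big[t + tau, , ] - mean(big[t + tau, , ])
        bs <- b[(s + 1 + eta):(s + 8 + eta), (s + 1 + xi):(s + 8 + xi)]
        acc <- acc + sum(a * bs) / 64
      }
      got <- co$values[which(co$eta == eta), which(co$xi == xi), tau + 1]
      expect_equal(got, acc / np, tolerance = 1e-10)
    }
  }
})

test_that("gaussian peak fit localizes sub-pixel centers", {
  xi <- -8:7; eta <- -8:7
  S <- outer(exp(-(eta + 0.5)^2 / 4), exp(-(xi - 1.5)^2 / 5)) + 0.1
  fk <- podopipe:::fit_gaussian2d_peak(S, xi, eta)
  expect_true(fk$valid)
  expect_equal(fk$xi_hat, 1.5, tolerance = 0.05)
  expect_equal(fk$eta_hat, -0.5, tolerance = 0.05)
  # symmetric noiseless peak at the origin
  S0 <- outer(exp(-eta^2 / 4), exp(-xi^2 / 4))
  f0 <- podopipe:::fit_gaussian2d_peak(S0, xi, eta)
  expect_equal(abs(f0$xi_hat) + abs(f0$eta_hat), 0, tolerance = 1e-6)
  # flat surface is invalid
  co_flat <- structure(list(values = array(1, c(8, 8, 2)), xi = -4:3,
                            eta = -4:3, max_tau = 1L), class = "stics_corr")
  expect_false(fit_correlation_peak(co_flat, 1)$valid)
  # peak on the window edge is invalid
  Se <- matrix(0, 16, 16); Se[1, 4] <- 1
  expect_false(podopipe:::fit_gaussian2d_peak(Se, xi, eta)$valid)
})

test_that("velocity conversion follows the calibration arithmetic", {
  cfg <- stics_config(pixel_size = 0.04, frame_interval = 15, intercept = TRUE)
  peaks <- data.frame(tau = 1:6, xi = 0.5 * (1:6), eta = 0, valid = TRUE)
  v <- velocity_from_lags(peaks, cfg)
  expect_equal(v$vx, 0.5 * 0.04 * 60 / 15)  # 0.08 um/min
  expect_equal(v$vy, 0)
  expect_equal(v$fit_r_squared, 1)
  # all peaks at the origin: zero velocity, still a valid (perfect) fit
  p0 <- data.frame(tau = 1:5, xi = 0, eta = 0, valid = TRUE)
  v0 <- velocity_from_lags(p0, cfg)
  expect_equal(c(v0$vx, v0$vy), c(0, 0))
  # doubling the frame interval halves the reported speed
  cfg2 <- stics_config(pixel_size = 0.04, frame_interval = 30)
  expect_equal(velocity_from_lags(peaks, cfg2)$vx, v$vx / 2)
  # fewer than 3 valid lags invalidates the vector
  p2 <- data.frame(tau = 1:6, xi = 0.5 * (1:6), eta = 0,
                   valid = c(TRUE, TRUE, rep(FALSE, 4)))
  expect_false(velocity_from_lags(p2, cfg)$valid)
})

test_that("noiseless lattice translation is recovered at every interior ROI", {
  withr::with_seed(11, {
    nx <- 96; ny <- 96; nt <- 12; px <- 0.04
    g <- seq(4, 92, by = 8)
    pts <- as.matrix(expand.grid(x = g * px, y = g * px))
    amp <- runif(nrow(pts), 80, 150)
    arr <- array(0, c(nt, ny, nx))
    for (t in 1:nt) {
      sh <- cbind(pts[, 1] + 0.3 * (t - 1) * px,
                  pts[, 2] - 0.2 * (t - 1) * px)
      arr[t, , ] <- podopipe:::render_spots(ny, nx, px, sh, amp, 1.0 * px)
    }
  })
  cfg <- stics_config(roi_size = 16, roi_shift = 8, toi_length = 10,
                      max_tau = 4, pixel_size = 0.04, frame_interval = 15,
                      immobile_modes_removed = 0)
  vf <- stics_vector_field(arr, cfg)
  interior <- vf$ix >= 1 & vf$ix <= max(vf$ix) - 1 &
    vf$iy >= 1 & vf$iy <= max(vf$iy) - 1
  expect_true(all(vf$valid[interior]))
  scale <- 0.04 * 60 / 15
  err <- pmax(abs(vf$vx[interior] / scale - 0.3) / 0.3,
              abs(vf$vy[interior] / scale + 0.2) / 0.2)
  expect_lt(max(err), 0.05)
  # determinism of the full chain
  vf2 <- stics_vector_field(arr, cfg)
  expect_identical(vf$vx, vf2$vx)
  expect_identical(vf$retained, vf2$retained)
})

test_that("similarity filtering keeps coherent fields and drops rebels", {
  g <- expand.grid(ix = 0:4, iy = 0:4)
  field <- data.frame(
    x_um = g$ix * 0.16, y_um = g$iy * 0.16, toi = 1, ix = g$ix, iy = g$iy,
    vx = 0.05, vy = 0, fit_r_squared = 1, valid = TRUE)
  field$magnitude <- sqrt(field$vx^2 + field$vy^2)
  field$direction <- atan2(field$vy, field$vx)
  f1 <- filter_noise_vectors(field)
  expect_true(all(f1$retained))
  # one reversed vector in the middle is eliminated, the rest survive
  mid <- which(g$ix == 2 & g$iy == 2)
  field$vx[mid] <- -0.05
  field$direction <- atan2(field$vy, field$vx)
  f2 <- filter_noise_vectors(field)
  expect_false(f2$retained[mid])
  expect_true(all(f2$retained[-mid]))
})

test_that("iid random fields retain at the combinatorial chance rate", {
  # neighbors agree when |angle diff| <= 45 deg AND ratio in [0.5, 2];
  # for unit-speed iid vectors the angle rule alone bites: p = 0.25.
  # retention = P(at least `need` of k neighbors agree) for interior
  # vectors with k = 8.
  p_agree <- 0.25
  need <- 3
  p_keep <- sum(vapply(need:8, function(k) {
    choose(8, k) * p_agree^k * (1 - p_agree)^(8 - k)
  }, numeric(1)))
  withr::with_seed(31, {
    kept <- 0; tot <- 0
    for (rep in 1:60) {
      g <- expand.grid(ix = 0:7, iy = 0:7)
      ang <- runif(64, 0, 2 * pi)
      field <- data.frame(
        x_um = g$ix * 0.16, y_um = g$iy * 0.16, toi = 1,
        ix = g$ix, iy = g$iy,
        vx = 0.05 * cos(ang), vy = 0.05 * sin(ang),
        fit_r_squared = 1, valid = TRUE)
      field$magnitude <- 0.05
      field$direction <- atan2(field$vy, field$vx)
      f <- filter_noise_vectors(field)
      interior <- g$ix >= 1 & g$ix <= 6 & g$iy >= 1 & g$iy <= 6
      kept <- kept + sum(f$retained[interior])
      tot <- tot + sum(interior)
    }
    expect_equal(kept / tot, p_keep, tolerance = 0.25)
  })
})

test_that("a static noisy scene yields almost no retained vectors", {
  withr::with_seed(17, {
    base <- podopipe:::render_spots(80, 80, 0.04,
                                    cbind(runif(6, 0.8, 2.4), runif(6, 0.8, 2.4)),
                                    120, 0.17) + 10
    nt <- 14
    arr <- array(0, c(nt, 80, 80))
    for (t in 1:nt) {
      arr[t, , ] <- matrix(rpois(6400, base) + rnorm(6400, 0, 3), 80, 80)
    }
  })
  cfg <- stics_config(roi_size = 16, roi_shift = 8, toi_length = 10,
                      toi_shift = 4, max_tau = 5,
                      pixel_size = 0.04, frame_interval = 15)
  vf <- suppressWarnings(stics_vector_field(arr, cfg))
  expect_lt(mean(vf$retained), 0.05)
})

test_that("mean velocity averages retained magnitudes", {
  f <- data.frame(magnitude = c(1, 3, 100), retained = c(TRUE, TRUE, FALSE))
  expect_equal(mean_velocity(f), 2)
  expect_equal(mean_velocity(f[2, ]), 3)
  expect_error(mean_velocity(f[3, ]), "no retained")
})
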