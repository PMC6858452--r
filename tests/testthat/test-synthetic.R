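# Synthetic scene generator: determinism, geometry and noise model.

test_that("identical spec and seed give bit-identical images", {
  sp <- small_scene()
  a <- simulate_cluster_image(sp)
  b <- simulate_cluster_image(sp)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$centers, b$truth$centers)
  # different seed changes the field
  c <- simulate_cluster_image(small_scene(seed = 43))
  expect_false(identical(a$image$data, c$image$data))
})

test_that("empty scene yields background-only image and no centers", {
  sp <- scene_spec(field_size = c(3, 3), n_podosomes = 0, background = 7,
                   read_noise_sigma = 0, seed = 1)
  sim <- simulate_cluster_image(sp, noise = FALSE)
  expect_equal(nrow(sim$truth$centers), 0)
  expect_true(all(abs(get_plane(sim$image, "core") - 7) < 1e-9))
})

test_that("ground truth FWHM obeys the Gaussian identity", {
  sp <- small_scene(core_sigma = 0.17)
  sim <- simulate_cluster_image(sp, noise = FALSE)
  expect_equal(sim$truth$true_core_fwhm, 2 * sqrt(2 * log(2)) * 0.17)
  expect_equal(sim$truth$true_core_fwhm, 0.4003, tolerance = 1e-3)
  expect_equal(sim$truth$true_ring_diameter, 2 * sp$ring_radius)
})

test_that("hard-core placement respects the minimum separation", {
  for (seed in 1:5) {
    sim <- simulate_cluster_image(small_scene(n = 8, seed = seed))
    d <- dist(cbind(sim$truth$centers$x_um, sim$truth$centers$y_um))
    expect_gte(min(d), 1.2)
  }
})

test_that("impossible density fails with an informative placement error", {
  sp <- scene_spec(field_size = c(3, 3), n_podosomes = 50,
                   min_separation = 1, margin = 0.5, seed = 1)
  expect_error(simulate_cluster_image(sp), "achievable density")
})

test_that("noiseless core intensity integrates to the photon budget", {
  sp <- scene_spec(field_size = c(4, 4), n_podosomes = 1, background = 0,
                   read_noise_sigma = 0, psf_sigma = 0.04, seed = 9)
  sim <- simulate_cluster_image(sp, noise = FALSE)
  total <- sum(get_plane(sim$image, "core"))
  expected <- sp$channel_amplitudes[["core"]] * 2 * pi *
    (sp$core_sigma / sp$pixel_size)^2
  expect_equal(total, expected, tolerance = 0.01)
})

test_that("z-stack places the dorsal channel at the requested plane", {
  sp <- small_scene(n = 5)
  zs <- simulate_zstack(sp, z_step = 0.1, dorsal_z = 0.5, noise = FALSE)
  tot <- vapply(seq_len(dim(zs$image$data)[2]), function(iz) {
    sum(get_plane(zs$image, "myosin", z = iz))
  }, numeric(1))
  expect_equal(which.max(tot) - 1, 5)  # 0-based plane index
  expect_equal(zs$truth$true_z_heights[["myosin"]], 0.5)
  expect_equal(zs$truth$true_z_heights[["ring"]], 0)
})

test_that("z range that cannot cover the dorsal plane is an error", {
  sp <- small_scene(n = 3)
  expect_error(simulate_zstack(sp, z_step = 0.1, dorsal_z = 0.5, z_max = 0.3),
               "does not cover")
})

test_that("pure drift translates frames rigidly (interpolation tolerance)", {
  sp <- small_scene(n = 5, background = 0, psf_sigma = 0)
  # 0.5 px/frame in x: v = 0.5 * 0.04 um/frame * 4 frames/min
  fl <- flow_spec(n_frames = 5, oscillation_amplitude = 0,
                  wobble_amplitude = 0, immobile_fraction = 0,
                  drift_velocity = c(0.5 * 0.04 * 4, 0), seed = 2)
  sim <- simulate_flow_series(sp, fl, noise = FALSE)
  f0 <- sim$image$data[1, 1, 1, , ]
  for (t in c(3, 5)) {
    ft <- sim$image$data[t, 1, 1, , ]
    shifted <- podopipe:::translate_bilinear(f0, 0.5 * (t - 1), 0)
    expect_lt(max(abs(ft - shifted)), 0.03 * max(f0))
  }
})

test_that("without oscillation or drift all frames are identical", {
  sp <- small_scene(n = 4)
  fl <- flow_spec(n_frames = 4, oscillation_amplitude = 0,
                  wobble_amplitude = 0, seed = 5)
  sim <- simulate_flow_series(sp, fl, noise = FALSE)
  for (t in 2:4) {
    expect_equal(sim$image$data[t, 1, 1, , ], sim$image$data[1, 1, 1, , ])
  }
})

test_that("oscillation phases decorrelate beyond the correlation length", {
  # pool pairs from several independent fields; phases are stored latent
  # field values, so the pair correlation estimates the field correlogram
  # correlogram of the latent phase field across independent draws at a
  # fixed hard-core point pattern of 100 podosomes
  sp <- scene_spec(field_size = c(15, 15), n_podosomes = 100,
                   min_separation = 1.0, margin = 0.8, seed = 1)
  withr::with_seed(sp$seed, {
    pts <- podopipe:::place_hardcore(sp$n_podosomes, sp$field_size,
                                     sp$min_separation, sp$margin)
  })
  withr::with_seed(77, {
    draws <- podopipe:::grf_at_points(pts, length_scale = 2.5,
                                      n_fields = 200)
  })
  d <- as.matrix(dist(pts))
  far <- which(upper.tri(d) & d > 9.5 & d < 10.5, arr.ind = TRUE)
  near <- which(upper.tri(d) & d < 1.5, arr.ind = TRUE)
  cor_of <- function(pairs) {
    mean(vapply(seq_len(nrow(pairs)), function(k) {
      cor(draws[pairs[k, 1], ], draws[pairs[k, 2], ])
    }, numeric(1)))
  }
  expect_lt(abs(cor_of(far)), 0.1)  # ~0 at 10 um for l = 2.5 um
  expect_gt(cor_of(near), 0.5)      # strong coherence below l
  # the phases handed to the oscillator are the latent field values scaled
  # by the configured dispersion (rad)
  fl <- flow_spec(n_frames = 2, correlation_length = 2.5, seed = 3)
  sim <- simulate_flow_series(sp, fl, noise = FALSE)
  expect_equal(sim$truth$oscillation_phase,
               fl$phase_dispersion * sim$truth$phase_latent)
})

test_that("gelatin assay controls the degraded area and depth", {
  sp <- scene_spec(field_size = c(8, 8), n_podosomes = 0, seed = 3)
  g0 <- simulate_gelatin_assay(sp, degraded_fraction = 0, noise = FALSE)
  expect_false(any(g0$truth$true_degraded_mask))
  m0 <- degradation_metrics(g0$image, g0$truth$cell_mask,
                            g0$truth$reference_mask)
  expect_equal(m0$mean_ratio, 1, tolerance = 1e-9)
  expect_equal(m0$degraded_area_fraction, 0)

  g2 <- simulate_gelatin_assay(sp, degraded_fraction = 0.2,
                               degradation_depth = 1, noise = FALSE)
  frac <- mean(g2$truth$true_degraded_mask[g2$truth$cell_mask])
  expect_equal(frac, 0.2, tolerance = 0.01)
  m2 <- degradation_metrics(g2$image, g2$truth$cell_mask,
                            g2$truth$reference_mask)
  expect_equal(m2$degraded_area_fraction, 0.2, tolerance = 0.01)
  expect_equal(m2$mean_ratio, 0.8, tolerance = 0.01)

  gd0 <- simulate_gelatin_assay(sp, degraded_fraction = 0.5,
                                degradation_depth = 0, noise = FALSE)
  v <- get_plane(gd0$image, "gelatin")
  expect_lt(diff(range(v)), 1e-9)  # depth 0: uniform image
})
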