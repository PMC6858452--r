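#!/usr/bin/env Rscript
# Generate the canonical synthetic scenes (cluster image, z-stack, flow
# movies, gelatin field), write them as TIFF + sidecar under results/data,
# and record the ground truth. Everything downstream (02-07) re-reads or
# regenerates these conditions from the same seeds.

suppressMessages(library(podopipe))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

message("cluster image: 100 podosomes, FWHM 0.40 um / ring 0.77 um, SNR ~10")
sim <- simulate_cluster_image(morphometry_scene(seed = seed))
write_image_series(sim$image, file.path(out, "cluster.tif"))
write.csv(sim$truth$centers, file.path(out, "cluster_centers_um.csv"),
          row.names = FALSE)

message("z-stack: dorsal (myosin) plane at 0.47 um, 0.1 um steps")
zs <- height_stack(seed = seed, dorsal_z = 0.47)
write_image_series(zs$image, file.path(out, "zstack.tif"))

message("flow movies: soft (l = 2.5 um) and stiff (l = 10 um) regimes")
for (regime in c("soft", "stiff")) {
  mv <- regime_movie(regime, seed = seed)
  write_image_series(mv$image, file.path(out, paste0("movie_", regime, ".tif")))
}

message("gelatin degradation field: 20% of the footprint fully degraded")
gel <- simulate_gelatin_assay(
  scene_spec(field_size = c(8, 8), n_podosomes = 0, seed = seed),
  degraded_fraction = 0.2, degradation_depth = 1)
write_image_series(gel$image, file.path(out, "gelatin.tif"))

message("wrote synthetic inputs to ", out)
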