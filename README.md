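# podopipe

Quantitative image analysis of **podosomes** — micron-scale protrusive
actin adhesions — in fluorescence microscopy, for cell biologists studying
adhesion nano-architecture and mechanosensing. The package implements, as
a tested R pipeline driven by a synthetic-data generator with exact ground
truth:

* **Radial morphometry**: podosome cores detected on the actin channel
  (multi-scale LoG), angularly averaged radial intensity profiles from a
  rotating ~3 um line, and Gaussian fits yielding the core FWHM
  (`2 sqrt(2 ln 2) sigma`, the 0.40 um scale) and the ring diameter
  (peak-to-peak `2R` of a mirrored-annulus fit, the 0.77 um
  alpha-actinin/gamma-actin and 1.02 um vinculin scales). Fits are
  accepted only when `R^2 > 0.95`.
* **Height analysis**: orthogonal (radial x z) views of z-stacks and
  Gaussian z-peak fits at chosen radial distances, e.g. the dorsal
  myosin-II plane near 0.47 um above the ventral network at r = 0.8 um.
* **Cluster morphometrics**: single-linkage cluster grouping, convex-hull
  areas, nearest-neighbor distances for clusters of >= 15 podosomes,
  radiating-filament lengths (skeleton tracing), intensity ratios, and
  gelatin-degradation indices.
* **twSTICS**: sliding-time-window spatiotemporal image correlation
  spectroscopy — Fourier immobile filtering, 16x16-px ROIs strided 4 px
  (75% overlap), 10-frame TOIs strided 1 frame (90% overlap, 2.5 min),
  per-lag correlation-peak tracking and velocity regression in um/min,
  with fit-quality and neighbor-similarity vector filtering.
* **PVC**: pair vector correlation
  `PVC(dr, dt) = (1/M_pairs) sum_i sum_j v_i . v_j` over vector pairs at
  spatial separation dr and temporal lag dt, plus the correlation-extent
  readout of mesoscale connectivity (soft-substrate-like short-range
  versus stiff-substrate-like cluster-wide coordination).

## Worked example

Simulate a 100-podosome cluster at the canonical imaging regime
(0.04-um pixels, SNR ~ 10), detect cores, and measure core FWHM and ring
diameter per podosome:

```r
library(podopipe)

sim <- simulate_cluster_image(morphometry_scene(seed = 11))
det <- detect_cores(sim$image, "core")

ctr <- c(det$coordinates$x_um[1], det$coordinates$y_um[1])
fit_gaussian_profile(radial_profile(sim$image, ctr, channel = "core"))
#> <profile_fit:single-gaussian-offset> fwhm=0.4066 um R2=0.9985 accepted
ring_diameter(radial_profile(sim$image, ctr, channel = "ring"))
#> <profile_fit:mirrored-annulus> fwhm=0.2500 um diameter=0.7640 um R2=0.9793 accepted
```

The first fit says this podosome's apparent core FWHM is 0.407 um
(generator truth 0.4003 um) with an accepted fit quality; the second says
its adaptor ring peaks 0.764 um across (truth 0.77 um). Over the full
field the accepted-fit means land within a few percent of truth; the
`analysis/02_radial_morphometry.R` driver prints

```
core FWHM:     0.407 +/- 0.008 um (n = 100 accepted; truth 0.4003)
ring diameter: 0.765 +/- 0.002 um (n = 53 accepted; truth 0.77)
```

Velocity mapping and connectivity on an oscillating-cluster movie:

```r
mv  <- regime_movie("stiff", seed = 1)            # 10-um phase coherence
res <- movie_connectivity(mv)                     # twSTICS + PVC
mean_velocity(res$field)                          # um/min
res$extent                                        # spatial extent, um
```

The `analysis/` scripts (01-07) run the full set of studies — scene
generation, morphometry, height analysis, cluster statistics, velocity
validation, connectivity regimes, degradation — and write their tables
under `results/`.

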