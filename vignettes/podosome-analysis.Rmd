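---
title: "Quantifying podosome nano-architecture and mesoscale dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying podosome nano-architecture and mesoscale dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podopipe)
```

## The measurement problem

Podosomes are micron-scale protrusive adhesion structures: a dense
branched-actin core about 0.5-0.7 um across, encased by a linear-actin
shell and an adaptor-protein ring (vinculin, talin), embedded in a network
of ventral and dorsal actin filaments that connects neighbours across a
cluster. `podopipe` implements the quantitative image-analysis chain used
to characterize this architecture and its mechanoresponse in fluorescence
microscopy:

* **Radial morphometry** — apparent core FWHM and ring diameter from
  angularly averaged intensity profiles with Gaussian fits;
* **Height analysis** — the axial position of ring, core and dorsal
  (myosin II-decorated) structures from orthogonal views of z-stacks;
* **Cluster morphometrics** — cluster grouping, convex-hull area,
  nearest-neighbor distances (NND), filament lengths, intensity ratios and
  gelatin-degradation indices;
* **twSTICS** — sliding-time-window spatiotemporal image correlation
  spectroscopy, mapping the velocity of fluorescent flows driven by
  podosome vertical oscillations;
* **PVC** — pair vector correlation, the mean dot product of velocity
  vectors versus their spatial separation and temporal lag, whose decay
  length reads out mesoscale connectivity.

Because the primary microscopy data behind these methods are not publicly
deposited, the package is organised around a **synthetic-data generator
with exact ground truth**. Every analysis stage is validated by recovering
known truth from simulations that emulate the statistical structure of the
real data; the `analysis/` scripts run these studies end to end and
`scripts/acceptance.R` reproduces the headline numbers.

## The synthetic scenes

`scene_spec()` fixes the imaging geometry: 0.04 um pixels, cores rendered
as isotropic Gaussians with `core_sigma` 0.17 um (apparent FWHM
`2 sqrt(2 ln 2) * 0.17 = 0.40` um), rings as Gaussian annuli peaking at
`ring_radius` 0.385 um (diameter 0.77 um, the alpha-actinin/gamma-actin
scale; 0.51 um gives the vinculin-like 1.02 um ring). Centers are placed
by hard-core rejection sampling with a bounded attempt budget — the
simplest point process consistent with the observed minimum spacing — and
an informative error names the achievable density when a request cannot be
met.

Photon arithmetic: the noiseless scene (structure + uniform background) is
blurred with a normalized Gaussian PSF (default 0.04 um, one pixel of
residual blur: the structural widths already describe the *apparent*,
optics-convolved sizes, so the residual PSF only adds ~3% in quadrature to
the 0.40-um core), then Poisson shot noise and Gaussian read noise are
applied. Absolute photon counts are rarely reported for this kind of
acquisition, so
the default photon budget was chosen once as a realistic confocal regime:
peak amplitude 120 photons over background 10 with 3-photon read noise,
giving peak SNR = `A / sqrt(A + b + r^2)` of about 10. Live-cell movies
use a brighter 250-photon amplitude, reflecting the stronger signal of
overexpressed live labels.

Z-stacks concentrate core and ring intensity at the ventral plane and a
myosin-like channel on an annulus of radius 0.85 um at `dorsal_z`
(default emulation: 0.47 um), each with a Gaussian axial profile
(`z_sigma` 0.15 um).

### Oscillating time-lapse movies

Podosomes oscillate vertically; in a fixed focal plane this appears as
intensity oscillation, and because neighbouring podosomes are mechanically
coupled through interpodosomal filaments, their oscillations are
coordinated over a characteristic distance. The generator realizes this
with a single tunable knob: per-podosome oscillation phases are
`phase_dispersion` (2 rad) times a unit Gaussian random field with
squared-exponential covariance of scale `correlation_length`. Soft
substrates are emulated with a 2.5-um scale, stiff substrates with 10 um.
2 rad of dispersion leaves a coherent cluster coherent while letting
phases decorrelate across scales larger than `correlation_length`; with pi
radians even the stiff regime desynchronizes, while with 1 rad the soft
regime never does — 2 rad is the regime that reproduces the qualitative
picture of stiff clusters oscillating in register against soft clusters
correlated only locally.

Intensity blinking alone produces no lateral translation for a correlation
tracker to follow, so the generator couples the same phase field to a
small lateral oscillation of each podosome: displacement
`wobble_amplitude * sin(2 pi t / period + phase) * e_i`, with unit
direction vectors `e_i` drawn from the same-scale random field. This
stands in for the traction-coupled lateral components of the vertical
oscillation cycle and gives locally coherent flows at the measured
physiological speed scale (wobble 0.12 um and period 360 s give peak
speeds of ~0.1 um/min; a uniform `drift_velocity` adds an exactly known
translation). The ground truth records phases, latent field values,
wobble directions and the drift field.

Two rendering features matter for correlation tracking. Cores in the
movies carry **granular texture**: `texture_n` sub-resolution speckles
(sigma `texture_sigma`, 0.06 um) at fixed random offsets inside the core
envelope, moving rigidly with the podosome, with the same integrated
intensity as the smooth core. Live actin labels resolve exactly this kind
of granularity, and it is what correlation tracking locks onto — a
perfectly smooth Gaussian core is measurably harder to track (its flanks
are pure gradients whose windowed correlation peak is biased toward
zero). An optional **network layer** (`network_density` speckles per um^2,
moving with the drift but not oscillating) emulates the interpodosomal
and cortical F-actin between podosomes.

What the generator deliberately does **not** emulate: real actin texture
(cores are smooth Gaussians), vectorial or depth-dependent PSFs,
photobleaching, stage drift, or the irregular shapes of real clusters.
Passing the recovery suites therefore demonstrates correctness of the
estimators under the stated statistical model, not robustness to every
property of real data.

## Radial profiling and fits

`radial_profile()` follows the rotating-line protocol: a two-sided line of
~3 um total length through the core center, rotated over `n_angles`
orientations in `[0, pi)` (default 180, i.e. 1-degree steps; profiles are
converged well below that), sampled by bilinear interpolation at
pixel-size steps, then averaged per distance. Lines that leave the image
are clipped and flagged. The estimator is validated against a closed-form
generatrix on rotationally symmetric scenes (agreement within 1% of peak)
and against direct index sampling for a single angle.

`fit_gaussian_profile()` fits either `A exp(-r^2 / 2 sigma^2) + c` or the
mirrored annulus
`A [exp(-(r-R)^2 / 2 sigma^2) + exp(-(r+R)^2 / 2 sigma^2)] + c` by
Levenberg-Marquardt with positivity bounds on widths; ring diameter is the
peak-to-peak distance `2R`, the only operational definition consistent
with a symmetric two-sided profile. Fits are accepted only when
`R^2 > 0.95`, strictly: a fit at exactly 0.95 is rejected. Fits run on
**unnormalized** averaged profiles; min-max normalization is
presentation-only, because normalizing first distorts the offset estimate.
Both per-podosome fits (used for population statistics) and fits of the
podosome-averaged profile are supported; per-podosome is the default mode
in the analysis scripts because population box plots require per-podosome
values.

Detection (`detect_cores()`) is multi-scale Laplacian-of-Gaussian blob
detection over core diameters 0.5-0.7 um, with greedy non-maximum
suppression at 0.5 um, sub-pixel refinement by a quadratic fit on the 3x3
response neighborhood, and a deterministic ordering (response descending,
ties by position). A manually curated centers table can be supplied
instead wherever centers are consumed — the semi-automatic escape hatch.

## Height analysis

`orthogonal_view()` applies the same rotating-line sampler per z-plane and
averages over angles and (optionally) podosomes, yielding a radial-by-z
map with its z axis anchored at the ventral reference plane (the plane of
maximum total intensity in a designated ventral channel, configurable).
`z_peak_height()` extracts the z-column at a requested radial distance
(0 um for the core, 0.45 um for vinculin, 0.8 um for myosin/network
actin), averages the +r and -r columns, and Gaussian-fits the axial
profile. Pooling the orthogonal views of all podosomes before fitting is
supported and used for the myosin channel, whose per-podosome signal is
too weak for reliable individual fits. On the canonical stack the dorsal
plane at 0.47 um is recovered within 0.01 um.

## twSTICS

The velocity chain follows the published protocol defaults: per-pixel
Fourier immobile filtering (DC removal by default; the number of removed
low frequencies is configurable), 16 x 16-px ROIs (0.64 x 0.64 um) strided
4 px for 75% spatial overlap, 10-frame TOIs (2.5 min at 15-s frames)
strided 1 frame for 90% temporal overlap. Per ROI/TOI the space-time
correlation is computed by zero-mean FFT cross-correlation per frame pair,
averaged per lag; the mean-product normalization is applied when frame
means are positive and falls back to unnormalized otherwise (after
immobile filtering spatial means are ~0; the peak position, the only
quantity consumed downstream, does not depend on the convention). Lags are
restricted to the TOI window (`max_tau <= toi_length - 1`).

The correlation peak at each lag is localized by an elliptical 2D Gaussian
(with offset) seeded at the discrete argmax and fit over its 7x7
neighborhood; peaks on the window edge are flagged invalid. Velocity is
the slope of the valid peak positions versus lag (free intercept by
default, which absorbs the lag-0 noise-spike bias; the fit starts at
`tau_min = 1` for the same reason), converted by
`v = slope * pixel_size * 60 / frame_interval`.

Two retention criteria follow. The **fit criterion** requires the lag
regression to have `R^2 >= 0.9`. The **similarity criterion** retains a
vector only when at least 3 of its up-to-8 same-TOI grid neighbors agree
within 45 degrees and a magnitude ratio of [0.5, 2]. Three agreeing
neighbors rather than two: with 75% ROI overlap, adjacent windows share
most of their pixels, so spurious vectors from one noise structure are
mutually consistent across neighbors and a 2-neighbor quorum passes them.

**Window truncation and the search option.** The correlation-peak
position of structure that leaves the fixed ROI during the lag is biased
toward zero — severely so for a spot exiting through the window edge
(slope ratio ~0.3 in a direct probe), and by order 10% for a
podosome-sized core (~11 px FWHM in a 16-px window). `search_pad` removes
this truncation: the lagged frame of each correlation is taken from the
ROI grown by `search_pad` pixels into the full recorded frame, so exiting
structure stays visible; measurable lags are then capped at `search_pad`.
The default configuration keeps the classic fixed-window behavior
(`search_pad = 0`), which is what the FFT-versus-brute-force oracle
checks; the drift-recovery study enables `search_pad = 6` and turns the
immobile filter off — nothing in that scene is static, and DC removal of
a drifting scene subtracts a motion-smeared streak whose correlation
biases speeds upward. With these choices the imposed 0.05 um/min drift
is recovered within ~5-8% across seeds. The end-to-end 5%-per-ROI
validation uses a lattice of fine spots with clean structure in every
window; it validates the estimator chain under ideal texture.

## PVC and correlation extent

`pair_vector_correlation()` implements the dot-product statistic directly:
over all pairs of distinct retained vectors, dot products accumulate into
(separation bin, temporal lag) cells and are divided by the pair count
`M_pairs`. Separation bins default to the ROI grid spacing; +dt and -dt
pairs are pooled (symmetric because the dot product commutes); cells with
no pairs stay undefined rather than zero. Raw dot products are the
default, matching the statistic as printed; unit-normalized mode bounds
values in [-1, 1]. Per-movie surfaces are averaged arithmetically across
replicates.

`correlation_extent()` operationalizes "correlated up to X um": starting
from the first adequately sampled bin (at least 5 pairs) at zero temporal
lag, it scans outward while the PVC stays above half the reference value
and reports where the run ends. The run-based scan (rather than "the
largest bin anywhere above threshold") matters on sparse fields, where a
single noisy far bin would otherwise set the extent. On the canonical
movies the soft regime (2.5-um phases) yields extents of ~1-2 um and the
stiff regime (10-um phases) saturates near the largest sampled separation,
strictly ordered in at least 95% of seeded replicate pairs.

## Cluster morphometrics

Clusters are formed by single-linkage grouping at a 2-um chain distance (a
package choice; the source protocols treat clusters as given per cell).
Cluster area is the convex hull of member centers; NND is the per-member
distance to its nearest co-member, reported only for clusters of at least
15 podosomes — smaller clusters are excluded, and the threshold is exact.
Gelatin degradation is the mean labeled-gelatin intensity under the cell
footprint normalized to non-degraded reference regions, plus a degraded
area fraction at a configurable threshold (default half the reference
mean). Intensity ratios (e.g. phospho-myosin over total myosin) subtract
each channel's out-of-mask median background first, so common offsets
cancel.

Filament lengths use top-hat background suppression, hysteresis
thresholding, Zhang-Suen skeletonization and branch tracing; a branch
whose traced path reaches within `core_radius` of a center is a radiating
filament, measured from the core boundary to its tip. Thinning erodes one
to two pixels from rounded tips, so tips are extended through the
half-maximum mask, putting measured endpoints on the FWHM convention;
noiseless straight segments are recovered within about one pixel. The
pipeline is this package's operationalization of what is in practice a
manual measurement; manually traced polylines can be measured instead by
skipping detection and supplying centers as `NULL`.

## Numerical choices and degenerate inputs

* All randomness flows from explicit integer seeds (`withr::with_seed`),
  so identical spec + seed is bit-identical, including camera noise.
* FFT blurs and correlations are circular; scenes keep structures away
  from edges (placement margins) so wrap effects are negligible, and
  photon totals are conserved exactly by the normalized kernels.
* Degenerate profile fits (flat input, non-convergence) return
  `accepted = FALSE` with a diagnostic rather than erroring; a mirrored
  annulus collapsing to `R ~ 0` warns and reduces to a single Gaussian.
* Flat correlation surfaces, peaks on window edges, and lag fits with
  fewer than three valid points all invalidate the vector rather than
  producing a number.
* Collinear clusters have hull area 0 with a degeneracy flag; empty masks
  and non-positive denominators are errors with explicit messages.

## Problem sizes

The validation studies are sized for a single CPU: 100-podosome fields
(20 x 20 um) for morphometry and height recovery, 6.4-um 20-frame movies
for the connectivity regimes (50 replicate pairs), 96-px lattices for the
translation oracle, and 200-replicate nulls for the PVC zero-mean
property. These sizes are stated here as the package's canonical study
conditions; all are constructed in code at run time, none are stored.

## Limitations

* The flow generator's lateral-wobble coupling is a minimal mechanical
  caricature; it produces the right observable (locally coherent flows at
  ~0.05-0.1 um/min) but is not a biophysical model of protrusion.
* twSTICS magnitudes on structures comparable to the ROI carry the
  truncation bias discussed above.
* Detection assumes planar (2D) seeding on the core channel, as in the
  original protocol; there is no 3D blob detection.
* No deconvolution, chromatic-shift correction, bleaching correction or
  cell segmentation; masks are inputs (or ground truth from the
  simulator).
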