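---
title: "Simulating and quantifying photoacoustic microvascular imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying photoacoustic microvascular imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`pamvasc` models an optical-resolution photoacoustic microscope (OR-PAM)
imaging self-assembled capillary networks in bioprinted hydrogel blocks, and
implements the complete downstream quantification: envelope reconstruction,
system characterization, 3D vessel morphometry, and rank-based group
statistics. Because no real acquisitions are distributed with the package,
a synthetic-phantom module provides ground-truth specimens against which
every stage is validated. This vignette records the model assumptions, the
tunable parameters, and the design decisions made where the design was
genuinely open.

## The forward model

**Transducer.** The detection transducer is described by its center
frequency $f_c$ (default 19 MHz) and fractional $-6$ dB bandwidth $B/f_c$
(default 0.69). Its impulse response is a zero-phase carrier under a
Gaussian envelope whose *spectral* $-6$ dB full width equals $B$. The
envelope duration, expressed as one-way depth, is then
$4\ln 2/\pi \cdot v/B \approx 0.88\, v/B$ — the familiar bandwidth-limited
axial resolution, 103.4 µm at the defaults with $v = 1540$ m/s.

**A-line synthesis.** Initial pressure is proportional to the absorber
concentration attenuated by a single-pass optical decay
$e^{-k_\mathrm{pam} z}$; each depth arrives at the one-way time of flight
$t = z/v$ (the acoustic wave travels specimen→transducer only, which also
resolves the 1540/500 = 3.08 µm "3 µm axial pixel" arithmetic) and is
convolved with the impulse response. The lateral excitation point-spread
function, FWHM $0.51\lambda/\mathrm{NA}$ (2.26 µm at 532 nm / NA 0.12), is
applied per depth slice in phantom space before A-line synthesis
(separable first-order approximation). Not modelled: acoustic attenuation
and diffraction, transducer focusing geometry, fluence, Grüneisen
variations — the instrument is treated as ideally focused, which the low
acoustic attenuation of hydrogel constructs makes a reasonable first-order
description.

**Attenuation calibration.** The attenuation coefficients are expressed
through the 1/e² penetration depth $d$ (depth at which intensity falls to
$e^{-2}$ of its extrapolated surface value): $k = 2/d$. Defaults are
$d = 431$ µm for the photoacoustic channel and $d = 262$ µm for the
confocal emulator — the bench values, so that the characterization module
recovers them; their ratio is the 1.6-fold penetration advantage.

**Noise.** Additive white Gaussian noise on the RF samples, standard
deviation 2% of the frame's peak RF amplitude (the instrument literature
rarely quotes SNR; 2% is a conservative bench-top figure). Noise is seeded
and fully reproducible; `noise_sigma = 0` gives a deterministic model.

**Confocal emulator.** Intensity = laterally blurred absorber ×
$e^{-k_\mathrm{lscm} z}$ + noise, clipped at zero. No RF stage; it exists
only to reproduce the penetration-depth comparison.

## Reconstruction

The A-line envelope is the magnitude of the analytic signal (FFT Hilbert
transform) — parameter-free and consistent with Gaussian-envelope fitting.
Envelopes are resampled by linear interpolation from the native 3.08 µm
sample pitch onto an exactly 3 µm axial lattice, so voxel bookkeeping
matches the nominal 2 × 2 × 3 µm voxel (`z_pitch_um = NULL` keeps the
native pitch). A 3 × 3 × 3 voxel median filter (replicate-padded) is the
standard despeckling step. Projections: per-pixel maximum over depth
(MAP), argmax depth masked below an Otsu floor (depth-encoded), and
B-scan slices.

## Characterization

- Lateral: ESF across a razor edge → central-difference LSF → FWHM by
  interpolated half-max crossings (no model fit). The razor-edge *fixture*
  defaults to a 2.42 µm PSF — the bench-measured LSF width — rather than
  the 2.26 µm diffraction limit, so the measured value round-trips through
  the full pipeline without pretending the first-order forward model
  explains the ~7% excess.
- Axial: least-squares Gaussian fit to the fiber envelope
  (`nls` with a `scaleOffset` guard so exact Gaussians converge), FWHM in
  depth units.
- Bandwidth: magnitude spectrum, $-6$ dB edges by linear interpolation;
  center frequency is the edge midpoint.
- Penetration depth: $I(z) = I_0 e^{-kz}$ by least squares on log
  intensity, $d = 2/k$; scale-invariant, errors on non-decaying input.

Two attenuation-profile estimators are provided. The slice-wise
`depth_attenuation_profile` (per-slice Otsu, size-filtered objects,
per-object median intensity) follows the obvious automation of manual
per-depth readings, but it is *biased when the axial point spread smears
each cell across many slices*: slice-wise thresholding preferentially
drops the dim tails of deep-seated cells, flattening the apparent decay by
roughly +10% on the photoacoustic channel. `cell_attenuation_profile`
instead takes one reading per cell at a strict 26-neighbourhood intensity
local maximum above a noise floor (5% of the volume maximum), which is the
automated equivalent of segmenting each cell once at its largest
cross-section; it is unbiased under smearing and does not lose deep cells
to a global threshold. The acceptance protocol pools three cell fields at
the bench loading density (2 × 10⁶ cells/mL ⇒ 2000 mm⁻³) and restricts the
exponential fit to depths at least one axial-resolution length inside the
acquisition boundaries, where pulses are not truncated.

## The synthetic phantom

A phantom is a hydrogel block (default 600 µm cube, so the three standard
0–200/200–400/400–600 µm analysis slabs exist) on the 2 × 2 × 3 µm voxel
lattice. Capillary networks grow from `n_sprouts = 12` seed points by a
sprout–elongate–branch walk:

- Segment arc lengths are log-normal. Medians are the observed per-day
  values (67.1 / 103.2 / 158.5 µm for culture days 4 / 6 / 8); the shape
  parameter is fitted per day so the 99.9th percentile matches the
  observed maxima (602.5 / 410.4 / 1154.7 µm — day 6's maximum is below
  day 4's, so a shared shape would be inconsistent).
- Walks step 3 µm with small angular noise that reverts to a fixed
  heading (guided elongation). Without the reversion term long walks
  hairpin onto themselves, which merges the tube with itself in voxel
  space and corrupts the traced topology.
- A finished segment either terminates or branches into exactly two
  daughters (per-day probability 0.35 / 0.45 / 0.55), so internal nodes
  have degree 3 and generated segments correspond one-to-one to
  branch-to-branch traced segments. Daughters form an opposed planar pair
  tilted 40–70° off the parent axis: same-side daughters would run merged
  for tens of micrometres.
- Radii are uniform 5–15 µm (capillary scale; no measurement constrains
  them).
- Growth is contact-avoiding: a spatial hash of grown centerlines steers
  sprouts away from other vessels with an 8 µm clearance — deliberately
  larger than the voxel diagonal (4.1 µm) so that 26-connectivity cannot
  bridge two "avoided" tubes after rasterization. Parent and sibling are
  touchable only while a daughter clears its junction ball (~45 µm).
  Sprouts boxed in early redraw their direction a few times before
  accepting truncation; root seeds resample until clear.

Rasterization uses flat-capped cylinders along each centerline (clamped
projection onto the polyline) plus joint spheres at interior vertices: the
flat caps make the voxel support end exactly at the centerline endpoints
(so traced lengths are comparable to ground truth without an end-cap
convention), and the joint spheres fill the wedge gaps between consecutive
cylinders, which would otherwise create topological tunnels that a
topology-preserving thinning must keep as loops.

Drug treatments prune segments by depth-dependent Bernoulli survival
(control 1.0; TMZ 0.55; SU 0.50; combination 0.25; each ×0.8 in the
shallow 0–200 µm slab near the spheroid seeding surface). These are
qualitative settings reproducing the reported ordering — strongest
suppression for the combination, most pronounced near the surface — not
quantitative claims.

What the generator does **not** emulate: real angiogenic biology (VEGF
gradients, anastomosis as a directed process, lumen formation), vessel
radius tapering, hydrogel heterogeneity, or specimen motion. A green
recovery test therefore establishes that the *measurement pipeline* is
faithful on networks with known geometry of the right scale — not that the
generator is a biological model.

## Vessel morphometry

Segmentation is a global Otsu threshold plus removal of 26-connected
components under 100 voxels (the reproducible stand-in for manual mask
refinement). Density is the vessel-voxel volume fraction per half-open
depth slab. Fractal dimension is 2D box counting (box sizes in powers of
two from 2 px to a quarter of the image) on a slab's binary maximum
projection.

Skeletonization is sequential 6-subiteration topological thinning with the
26/6 simple-point characterization and curve-endpoint preservation,
yielding a one-voxel curve skeleton. Tracing then builds segments between
skeleton voxels of degree ≠ 2 (26-adjacent node voxels merged into
clusters), splitting pure cycles at their lowest-linear-index voxel.

Measuring capillary-scale networks (tube diameters 10–30 µm against a
67–158 µm median segment length) required several cleanup steps, all
validated against generator ground truth and none tuned on the published
medians:

- **Adaptive spur pruning**: terminal skeleton branches shorter than
  1.3 × the local tube radius at their junction (and below a 25 µm cap)
  are thinning artifacts — branches from the medial axis to a bump on the
  tube surface — and are deleted; genuine short daughters survive.
- **Junction-stub fusion**: inside a thick junction ball the skeleton
  often carries two or three branch voxels joined by short internal stubs
  (or a tiny loop). An internal chain is classified as bookkeeping of a
  single anatomical branch point when its endpoint separation is below
  1.3 × the summed local radii at its ends (the two "branch points" sit
  inside each other's junction balls) *and* its waist stays wide (mid-chain
  local radius at least 0.75 × the smaller endpoint radius — a genuine
  short vessel narrows to its own tube radius between junctions, a stub
  does not). Such stubs are removed, with half their length credited to
  every segment attached at either end; nodes left with exactly two
  attached segments are then merged.
- **Path smoothing**: arc length is integrated over a boxcar-smoothed
  (±2 voxels) copy of each voxel chain, suppressing the staircase
  inflation of digitized curves while remaining exact for straight chains.
- **Tip compensation**: thinning erodes free tube ends; a sub-voxel ray
  march from each tip along the local tangent measures the distance to the
  mask boundary, credited up to the local radius and at most two voxel
  pitches (a ray that stays inside much longer than the local radius is
  not at a cap and gets nothing).
- **Cluster-centroid credit** (off by default): segments end at the rim
  of a junction cluster and could be extended by the rim-to-centroid
  distance; on validation networks the anatomical branch point turns out
  to sit at the rim where the branch attaches, so the default credit is
  zero and the knob is kept for sensitivity analysis.

On straight or obliquely oriented cylinders (length 50–1000 µm, radius
5–15 µm) the traced length is accurate to 5% + 2 voxel pitches. On full
day-4/day-8 networks, pooled traced medians recover the generator's
ground-truth medians to within about +5% / −8% respectively; the residual
day-8 deficit comes from junction balls splitting long segments — at these
tube diameters a bifurcation occupies a 30–60 µm blob whose internal
geometry no blind tracer can fully disambiguate, and the same limitation
applies to tracing real images of comparable vessels.

## Statistics

Kruskal–Wallis with tie correction and Dunn's pairwise z-tests with
Bonferroni adjustment are implemented directly from the rank formulas
(mid-ranks; tie terms $\sum(t^3-t)$), with the usual significance-tier
labels (**** < 10⁻⁴ through ns ≥ 0.05). The chi-square omnibus
approximation is standard; the test suite checks it against base R's
`kruskal.test`, an exhaustive permutation distribution at $N = 9$, a
20,000-draw label-permutation oracle for the Dunn z-tests, and a type-I
error calibration (rejection rate at $\alpha = 0.05$ within
[0.035, 0.065] over 2000 null replicates). The nonparametric path is
always taken; no parametric branch exists.

## Numerical and interchange choices

- Volumes travel as uncompressed 32-bit-float multi-page TIFF, one page
  per depth slice, with voxel pitch in a JSON ImageDescription tag. The
  reader refuses compressed or truncated files. (No TIFF package exists in
  the supported R stack, so the minimal subset of the format is
  implemented in-package and cross-checked against Python's `tifffile` in
  the test suite.)
- Run configuration is a single JSON document mirroring
  `default_config()`; unknown keys are rejected, missing keys filled with
  defaults. Every pipeline run writes a manifest with MD5 checksums;
  identical configs give identical artifacts.
- RF frames persist as raw little-endian float64 plus a JSON sidecar.
- All stochastic stages take explicit integer seeds; identical seeds give
  bit-identical outputs.

## Known limitations

- The forward model is first-order: no acoustic diffraction, attenuation,
  or focusing geometry; measured-vs-theoretical axial resolution
  differences (96.1 vs 103.4 µm on the bench) are out of scope.
- The day-8 traced-median recovery sits ~8% below ground truth (junction
  splitting, above), near the edge of the 10% acceptance band; day 4 sits
  ~+5% above. Both are properties of tracing thick-walled networks, not of
  the statistics.
- The slice-wise attenuation profile is biased under axial smearing; use
  the per-cell profile for decay fitting.
- The focal-length metadata (11.6 mm) is carried but unused; the quoted
  travel time for it is inconsistent with 1540 m/s and plays no role in
  any computation.
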