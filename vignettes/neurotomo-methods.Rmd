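---
title: "Simulating and quantifying Golgi-Cox micro-CT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying Golgi-Cox micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotomo)
```

## What the package models

Golgi-Cox staining deposits mercury in a sparse subset of neurons —
of the order of 3–10% of cells — and mercury's high atomic number makes
those neurons strongly X-ray absorbing. A synchrotron parallel-beam
micro-CT scan of such a sample therefore images bright somata
(10–25 µm) and thin neurites (radii near or below the voxel size)
against a dim tissue background, and cell counting reduces to
threshold-based segmentation of the reconstructed 8-bit volume.

`neurotomo` implements this entire chain on synthetic data with known
ground truth: phantom generation, parallel-beam acquisition (including
the offset-rotation-axis 360° extended-field-of-view mode), filtered
back-projection, non-local means denoising, the threshold-and-morphology
segmentation recipes, and two-group density statistics. Because every
cell in a phantom is known, the pipeline's counting performance can be
measured (precision, recall, F1, density error) rather than assumed.

## The phantom model

A `phantom_spec` describes a tissue block on a voxel grid (`z` is the
rotation axis; voxel centres at `(i + 0.5) * voxel_size`, 0-based
indices). Its components:

* **Tissue mask.** An ellipsoid with semi-axes 0.48 of each grid extent
  (a dissected tissue block that fits the scan), or the full grid. The
  embedding medium fills the inscribed scan cylinder — the region a
  rotating acquisition can reconstruct — and the volume outside the
  cylinder is empty. Reference volumes for densities are counted in
  voxels of the rasterised mask, so the density denominator is exactly
  the volume the segmentation sees.
* **Somata.** The number of stained cells is Poisson with mean
  `density_mean × tissue volume`; the four default densities follow the
  group summaries in `golgi_density_presets()` (31.08/27.32 cells/mm³
  cortex, 38.51/19.32 cells/mm³ hippocampus, each ± a between-animal
  SD, n = 5). These are densities of *stained* cells only; the phantom
  realises the stained population directly and does not model the far
  denser unstained tissue, which the stain contrast renders invisible
  to the counting procedure anyway. Somata are spheres with diameters
  uniform in 10–25 µm, placed by rejection sampling with two
  constraints: centres separated by at least the sum of the two radii
  (no overlap) and every soma entirely inside the tissue. The sphere
  shape makes the equivalent-diameter ground truth exact; the
  10–25 µm default brackets the 9 µm counting filter from both sides so
  the filter is genuinely exercised.
* **Neurites.** Each cell grows 2–5 neurites as persistent random
  walks: unit steps of one voxel length, turning at most 30° per step,
  starting at the soma centre and exiting through its surface, so every
  neurite voxel is 26-connected to its soma. Radii are drawn from
  0.5–2 µm — deliberately straddling the voxel size at the low-res
  pixel scale, because blurred, resolution-limited neurites are the
  regime that makes automatic whole-neuron segmentation hard in real
  scans. A walk terminates at its sampled length (20–120 µm) or when it
  leaves the tissue.
* **Attenuation.** Background 0.05, tissue 0.5, stain 5.0 mm⁻¹
  (≈10:1 stain:tissue contrast; the real data support "clearly
  observed" contrast but publish no coefficients). Somata are rasterised
  at full stain attenuation. Neurite voxels mix stain into their
  surroundings by the partial-volume fill fraction
  `min(1, πr²/voxel²)` — the fraction of the voxel cross-section the
  tube occupies — so sub-resolution neurites image dimmer than somata.
  Without this, 1 µm neurites would rasterise as bright 4 µm rods,
  neurite trees would be segmented as parts of "cell bodies", and
  centroids and diameters would be badly distorted; with it, thin
  neurites sit below the cell-body threshold exactly as in real scans.

All randomness is seeded; one global seed derives per-stage seeds by
hashing the stage name (`stage_seed()`), so a config and seed reproduce
every table bit for bit and any stage can be re-run in isolation.

## Acquisition and reconstruction

The projector is voxel-driven and parallel-beam: each voxel deposits
its attenuation × voxel length onto the detector bins overlapped by its
projected footprint of width `|cos θ| + |sin θ|` pixels (the exact
shadow of a square voxel). This conserves the per-slice integral to
machine precision at every angle and avoids the diagonal moiré of
two-bin splatting. The monochromatic approximation stands in for the
beamline's pink beam: the analysis never uses spectral information, and
beam hardening is out of scope. An optional anisotropic Gaussian PSF
(`apply_projection_psf()`, defaults 3 µm horizontal / 1 µm vertical)
emulates the source-size penumbra; it is off by default because the
default voxel sizes already exceed it. Counts follow Beer–Lambert with
Poisson noise at a configurable flat-field flux (default 20 000
counts/pixel); flats are Poisson realisations of the bare flux, darks
zero. Flat-field correction clips the transmission ratio at 10⁻⁶ and
logs how many values hit the clip.

**Extended FOV.** The rotation axis maps to a detector pixel *boundary*
(`detector_width/2 + axis_offset`), so opposed projections are
pixel-aligned and a 360° scan with integer offset composes exactly: the
view at θ + 180° is mirrored about the axis and joined to the view at
θ, giving a 180° sinogram on a virtual detector of
`detector_width + 2·axis_offset` pixels (2048 px with a 512 px offset
→ 3072 px, the published configuration). The doubly covered band is
blended with a linear ramp across its full width; ramp blending
suppresses seam artefacts that a hard cut would leave, which matters
because a seam crossing a soma could split one cell into two counts.

**FBP.** Reconstruction is filtered back-projection with the exact
band-limited Ram-Lak kernel (optional Hann apodisation) and linear-
interpolation back-projection, scaled π/n_angles, output in mm⁻¹ on the
detector grid. The published pipeline used a different analytic
reconstruction (BST, cited by reference only) — the downstream analysis
is reconstruction-agnostic, and FBP has the advantage of being
oracle-checkable: a 512-px disk phantom at the Crowther-satisfying 804
angles reconstructs with RMSE ≈ 0.4% of its attenuation (the test
budget allows 5%).

**Angular sampling.** `crowther_required_projections(w) = ⌈πw/2⌉`; for
a 2048-px object that is 3217, more than the 2048 projections actually
collected — the published scans knowingly undersample, and the default
pipeline mirrors that practice with `⌈2n/3⌉` projections for an n-px
grid. Streak artefacts from undersampling are part of what the
segmentation must tolerate.

**8-bit conversion.** Linear mapping of a percentile window to 0–255,
rounding half away from zero (documented so threshold tests are
bit-stable), percentiles rather than min/max so isolated hot pixels
cannot compress the gray range. Function defaults are P0.5–P99.5. The
phantom pipeline presets use P0.5–P99.999: stained voxels occupy of the
order of 0.01–0.1% of the volume, so a 99.5th percentile would sit in
the *tissue* intensity tail and saturate tissue to 255; anchoring the
window top inside the stain population keeps the three materials
separable (tissue ≈ 25–45 gray, stain ≈ 200–255) while remaining
robust to single hot pixels. Whether denoising preceded or followed
8-bit conversion in the original processing is unstated; here NLM runs
on the 8-bit volume, since the published gray thresholds are defined on
that scale.

## Denoising

Non-local means, slice-wise 2D by default, with Gaussian patch
weighting (patch radius 2, search radius 5) and the noise-compensated
weight `exp(−max(d² − 2σ², 0)/h²)`; `h = 0.8 σ` with σ estimated by a
robust median-absolute-difference estimator. These parameters are
unpublished; the defaults are common NLM practice and all are exposed.
The output is a convex combination of input grays, so the 0–255 range
is preserved; tests verify ≥50% noise-SD reduction on flat regions,
mean preservation within one gray level, and step-edge localisation
within one voxel.

## Segmentation

`segmentation_params()` defaults record the published recipe: watershed
brain seeds 130–255 and background seeds 0–126 (the nominal "256" upper
bound on 8-bit data is read as 255), cell bodies 142–255 followed by a
ball dilation and a "larger than 9 µm equivalent diameter" filter,
neurons 139–255 with closing and island removal. Design choices the
recipe leaves open:

* **"Diameter"** is implemented as equivalent spherical diameter
  `(6·n·v/π)^{1/3}` from the voxel count — orientation-free and robust;
  the running-text variant of the cutoff (10 µm) is the same config
  key. Digitised spheres ≥10 voxels across recover their diameter
  within 5%.
* **Measurements on pre-dilation voxels.** Dilation exists to
  consolidate fragmented somata into one component; measuring on
  dilated masks would inflate every diameter by two voxels. So
  components are formed on the dilated mask but measured on their
  pre-dilation voxels.
* **Connectivity 26** by default, matching the visual continuity of
  thin neurites; structuring elements are digital balls (radius 1 by
  default). Component labelling is deterministic (components numbered
  by raster order of their first voxel) and is verified against an
  independent minimum-label-propagation oracle.
* **Brain mask.** Marker-based watershed (priority flood, 6-connected)
  on the gradient magnitude, largest component kept, interior holes
  filled. On phantom reconstructions the pipeline presets override the
  seed gray ranges to 34–255 / 0–12: the published 130/126 split
  describes real tissue scans whose gray distribution differs from the
  three-material phantom (tissue ≈ 40 gray under the stain-anchored
  window above). The published values remain the function defaults.
* **Manual steps** (brush correction, manual tracing) are replaced by
  optional seed points that select components; interactive editing is
  out of scope, as is separating touching cells — clusters merge into
  one component here exactly as they did in the original counting.

## Quantification and statistics

Density = object count / reference volume, with the segmented tissue
mask as the default denominator ("mask" basis); whether the original
densities divided by structure volume or total imaged volume is
unstated, so the full-FOV basis is one option away. Detection
validation matches detected centroids to ground-truth centres greedily
in order of increasing distance within 10 µm, each matched at most once
— at ~30 cells/mm³ the nearest-neighbour ambiguity that optimal
assignment would resolve essentially never arises, and greedy matching
is deterministic.

Group comparison is the pooled-variance Student's t
(`df = n₁ + n₂ − 2`), matching the published analysis; Welch's form is
a flag. From the published summaries the test reproduces t = 7.87
(cortex) and t = 7.49 (hippocampus), both p < 10⁻⁴ at n = 5 per group.
The cortex SDs (0.5678, 0.9050 at n = 5) are strikingly small relative
to the hippocampal ones; they are used exactly as printed, without
reinterpretation as standard errors.

## Validation phantom sizes (and why)

Problem sizes are chosen so that the statistical tolerance being tested
is achievable in principle, then fixed:

* **Smoke preset**: 256 × 256 × 128 voxels at 4.5 µm (≈0.35 mm³ of
  tissue, ~11 expected cells) — exercises every stage in ~30 s but is
  too small for density accuracy: at 11 expected cells, Poisson
  fluctuation alone is ±30%.
* **Validation preset**: 512 × 512 × 256 voxels at 4.9 µm (≈3.5 mm³,
  ~135 expected cells at the hippocampal control density). Poisson
  fluctuation is then ~8.5% SD, comfortably inside the ±15% density
  error budget the end-to-end check uses, while one full pipeline run
  stays under ~10 minutes on one CPU. The voxel size sits just under
  half the smallest soma diameter, the resolvability bound that
  `phantom_spec()` validation enforces.
* **Group-experiment grid**: 352 × 352 × 176 voxels at 4.9 µm
  (≈1.2 mm³ per replicate). With the published between-animal SDs plus
  Poisson counting noise at this volume, the expected effect size gives
  the 5v5 pooled t test ≈97% power at α = 0.05, so ≥90% of 20 seeded
  runs reaching significance is the expected outcome, not a knife-edge.
* The full published geometries (2048-px detector at 0.82/4.11 µm,
  2048 projections over 360°, 512-px offset) are available as presets
  (`cortex-hires`, `hippocampus-lowres`) for parameter echo and
  scaled-down runs; at full scale they are cluster-sized volumes
  (3072² × 2048).

## Numerical choices and degenerate inputs

* Transmission ratios clip at 10⁻⁶ before the log; absorbance clips at
  0; both are counted and reported.
* A constant volume cannot be windowed to 8 bits: the result is all
  zeros with a warning.
* Zero expected cells yield an empty (valid) ground-truth table; an
  impossible packing (separation constraint unsatisfiable) aborts with
  the constraint named.
* Zero pooled variance: equal means give t = 0, p = 1; unequal means
  are an explicit error (infinite t) rather than a silent `Inf`.
* Composition with a centred axis is refused (use a plain 180°
  pipeline), except as an explicit degenerate identity under hard
  blending.
* Erosion treats out-of-grid voxels as background, so masks erode at
  the volume border.

## What passing tests do and do not show

The phantom reproduces the *contrast regime* (sparse bright cells, thin
dim neurites, dim tissue, photon noise, angular undersampling, the
offset-axis geometry) and the published densities. It does not
reproduce real neuroanatomy: no cortical layers or hippocampal
subfields, no glia, no staining artefacts ("scattered reflexive
granules"), no ring artefacts or beam hardening, no sample drift. A
perfect F1 on the validation phantom therefore demonstrates that the
*pipeline* counts what the segmentation recipe defines as a cell, at
realistic contrast and density, on an idealised sample; it does not
certify performance on real scans, where mask seeds and thresholds are
data-dependent and manual correction was part of the original
procedure. The package's claim is reproducibility and testability of
the computational chain, not biological equivalence.

## Known limitations

* Parallel-beam, monochromatic physics only; no phase contrast, no
  cone-beam, no detector/scintillator model.
* Destriping and illumination flattening (the "periodic noise and
  nonuniform brightness" preprocessing of the original pipeline) are
  not implemented.
* NLM is O(voxels × search-window) and single-threaded; full-scale
  (2048³) volumes need tiling or a cluster.
* The 16-bit TIFF label writer caps at 65 535 objects per volume.
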