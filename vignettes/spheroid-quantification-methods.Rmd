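---
title: "Methods: quantifying spheroid cultures from label volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying spheroid cultures from label volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spheroidquant` quantifies spheroid cultures at three scales — whole-spheroid
brightfield morphometry, single-cell 3D volumetrics, and subcellular
intensity ratios — from instance-segmentation label volumes and raw intensity
images. This vignette explains each model and procedure, the parameters that
matter, the numerical choices, and what the bundled synthetic generator does
and does not emulate.

## Data model

Volumes are plain R arrays with `dim = (y, x, z)`; label volumes are integer
arrays with 0 as background and positive ids as object instances; intensity
volumes share the same grid. All physical quantities use micrometres, with
voxel spacing carried as a named vector (default `c(z = 1, y = 0.473,
x = 0.473)`, the lateral pitch and z-step of a typical 1024×1024 confocal
acquisition of cleared spheroids). TIFF I/O stores the spacing in a JSON
sidecar next to each file because the plain TIFF writer does not emit
OME-XML; `read_volume()` accepts an explicit spacing override, and any
operation needing physical units fails loudly when spacing is absent rather
than assuming isotropy.

## 2D brightfield morphometry

The spheroid is segmented by global two-class Otsu thresholding of the
(dark-on-bright) image, hole filling and largest-component selection. The
diameter is the equivalent-circle diameter `2·sqrt(A/π)` — robust to boundary
roughness, unlike caliper measures. Eccentricity comes from the second
central moments of the mask: with eigenvalues `λ₁ ≥ λ₂` of the pixel
covariance, `e = sqrt(1 − λ₂/λ₁)`, which coincides with the analytic
eccentricity for exact ellipses, is 0 for a circle, and is invariant to
rotation (tests bound the rotational wobble at discretization level,
< 0.02).

The dissociated-cell ("loose cell") readout smooths the image with a
Gaussian (σ = 5 px), applies Otsu again, labels the foreground, discards
every object intersecting the main-spheroid mask, keeps objects whose
equivalent diameter falls in an inclusive 5–200 px band, and reports the
kept pixel area as a percentage of the whole image. Two interpretation
choices were open and are fixed as follows: "object diameter" is the
equivalent-circle diameter (the convention of common image-cytometry size
gates), and the denominator is the full image area rather than a region of
interest. The upstream pipeline this replaces used a learned pixel
classifier before thresholding; plain smoothing + Otsu is sufficient for the
synthetic images and for reasonably uniform backgrounds, but on plates with
strong background texture a pre-normalization step would be needed — the
smoothing also suppresses satellites smaller than roughly the smoothing
scale, so the measured percentage is a floor, not an unbiased estimate.

## 3D volumetrics

Nuclei are filtered by physical volume: anything below 300 µm³ or above
3,000 µm³ is treated as debris or a segmentation artifact. The band is
inclusive — exactly 300 µm³ survives — because the exclusions are defined as
strictly "less than" / "greater than".

The spheroid mask is reconstructed from the surviving nuclei by 40 iterations
of binary dilation followed by 40 iterations of binary erosion with the
connectivity-1 (6-neighborhood cross) structuring element, then hole filling,
then largest-component selection, in that order. Forty dilations bridge
inter-nuclear gaps up to 80 voxels while the matching erosions return the
outline to its original extent, so the closing fills the interior without
inflating the spheroid. Two deliberate numerical choices:

* **Voxel space, not physical space.** The iterations run on the voxel grid
  even though the grid is ~2.1:1 anisotropic, so gaps close over 40 µm
  axially but ~19 µm laterally. This mirrors the original grid-based
  procedure and is kept for reproducibility; an isotropic alternative would
  resample first.
* **Implementation.** k iterations of dilation with the 6-neighborhood equal
  a city-block distance threshold at k, so the package computes one
  multi-source breadth-first search (C++) instead of 40 passes; erosion is
  the dual with out-of-volume voxels treated as background (the zero-padded
  convention). Tests pin both against a literal shift-based implementation,
  voxel for voxel, and the acceptance script repeats that check at the full
  40 iterations on a 128³ fixture.

The generator leaves a ≥ 45-voxel clear margin on every face so the dilation
never clamps at the border; `reconstruct_spheroid_mask()` warns when given
data with a smaller margin and clamps at the faces.

Density divides the number of nuclei inside the mask by the mask volume. A
nucleus is "inside" when its centroid voxel is — partial-overlap handling was
unspecified in the source procedure, and centroid membership makes the count
insensitive to boundary voxels. The void region is the mask volume minus the
nuclear voxels inside it; volume, void and nuclear-inside volume satisfy an
exact conservation identity that the tests assert. The Ki-67 index is
`100·n⁺/n`.

## Subcellular N/C ratios

Nucleus-to-cell association uses a configurable overlap score with a 0.5
threshold and greedy one-to-one assignment in descending score order (ties:
ascending cell id, then nucleus id — determinism). The score defaults to
*nucleus coverage*, |N∩C|/|N|, rather than strict IoU |N∩C|/|N∪C|: a nucleus
occupying half its cell scores ~0.5 under coverage but only ~⅓ under IoU, so
a strict-IoU 0.5 gate would reject essentially every correct nucleus-cell
pair. Upstream tools describe the same knob as "minimum percentage overlap",
which reads as coverage; strict IoU remains available (`metric = "iou"`) and
both are tested. This is the module's main interpretation risk and the
reason the metric is exposed.

Cytoplasm is the matched cell's voxels minus its nucleus's voxels, carrying
the cell id. Compartment means are Σ intensity / voxel count; the background
— the mean over all voxels outside the detected cells (a median option
exists) — is subtracted from both before the quotient. Cells with an empty
cytoplasm or a non-positive corrected cytoplasmic mean are excluded and
tallied in a QC count rather than clamped, avoiding silent bias. Adding a
constant to the whole volume leaves every ratio unchanged (the background
absorbs it), and positive gain leaves ratios unchanged when the background is
zero; both invariances are tested. Ki-67 objects are assigned to the cell
containing the largest fraction of their voxels provided that fraction is at
least 0.5 — the alignment rule upstream is by shared id only, so
majority-overlap is the neutral criterion.

## Spatial profiling

A convex hull is built over all cell centroids (own incremental
implementation: starting from an extreme tetrahedron, each outside point
removes its visible faces and is stitched to the horizon edges; outward
orientation is maintained). The hull "center" is the polyhedron's volume
centroid, which is robust to uneven surface sampling; the mean of the input
points is also reported. Each cell's depth is computed by casting the ray
from the center through the centroid, intersecting it with the triangulated
surface (vectorized ray-triangle tests; nearest forward hit; ties broken by
the smallest face index) and measuring the distance from the intersection to
the centroid. Centroids that fall outside the hull by floating error clamp
to depth 0; a centroid coinciding with the center has no ray direction and
returns the minimum center-to-face distance with a warning. On spherical
shells of 500 points the depth matches the analytic `R − r` within 2% of R —
the residual is hull-facet sag, which shrinks with surface sampling density.
`radial_profile()` bins records into equal-width depth bins over
`[0, max depth]` and reports per-bin mean/median N/C ratio, Ki-67⁺ fraction
and counts, keeping empty bins visible.

## Cryosection differentiation

Per channel, each z-plane gets a focus score — the variance of a discrete
(5-point) Laplacian, a standard parameter-free sharpness measure, chosen
because the source procedure names no criterion — and the three best planes,
adjacent or not, are summed. Channels are median-filtered (radius 2 px) and
thresholded with Otsu (the thresholding method was unstated; Otsu is used
consistently with the brightfield stage). The whole-spheroid area is
segmented automatically (threshold, largest component, closing, hole fill),
replacing the manual wand-tool selection of the original workflow — a
documented deviation. Integrated density is mean intensity × (segment area /
spheroid area), algebraically equal to the segment's intensity sum divided
by the spheroid area (asserted as an identity in tests), and differentiation
is the Involucrin/CK14 ratio of integrated densities, which is exactly
invariant to common gain.

## The synthetic generator

`generate_spheroid()` packs spherical (in physical units; ellipsoidal in
voxels) cells inside the spheroid radius by rejection sampling — simple, and
sufficient for exercising mask arithmetic; no Voronoi partitioning. Each
cell carries a concentric nucleus scaled to half the cell volume by default,
guaranteeing containment by construction. Default geometry (6.5 ± 0.5 µm
cell radius) puts nuclei at ~575 µm³, inside the 300–3,000 µm³ filter band
as real nuclei would be. Rejection packing saturates near 30% of the
accessible volume, so feasible defaults stay below that; an infeasible
request fails with the achievable count in the message. The Ki-67⁺
subpopulation is drawn uniformly (no radial bias by default — no generative
model for it is stated anywhere, so uniform is the neutral choice), and the
Ki-67 object is the cell's nucleus, as for a nuclear antigen.

Intensities are set analytically per compartment: the `yap` channel gets
cytoplasm `b + A` and nucleus `b + r·A`, where `r` interpolates linearly in
distance-to-rim between `nc_ratio_center` and `nc_ratio_rim`, so with zero
blur and noise the measured background-corrected N/C ratio equals the
programmed one exactly (to 1e-9 and better; tests assert it). Blur and noise
are applied after this construction, which lets tests separate algorithmic
error from imaging degradation: under σ = 1 voxel blur and noise at 5% of
the signal the median recovery error across 200 cells stays under 15%. All
randomness flows from one integer seed; repeated generation is
voxel-identical.

What the generator does **not** emulate: optical point-spread anisotropy and
depth-dependent attenuation (the data it mimics was acquired with
z-compensation), segmentation errors beyond what blur/noise induce
(label volumes are ground truth by construction), irregular cell shapes, and
the nuclear-volume distributions of any particular cell line. Passing tests
therefore demonstrate that the *quantification chain* is correct and stable
under mild degradation — not that any specific biological effect size would
be recovered from real microscopy.

## Orchestration and reproducibility

`run_all()` executes generator → filter → closing → density/void → matching
→ cytoplasm → N/C → Ki-67 → hull → radial profile from a single YAML-or-list
configuration (unknown keys rejected; defaults: a 25-cell, 36 µm spheroid —
small enough to run in seconds yet large enough for a meaningful hull). The
resolved configuration is written into the output directory, and
manifest.json records the package version, a SHA-256 hash of the resolved
configuration (excluding the output path, which is run metadata) and SHA-256
checksums of every output file. Wall-clock timing goes to a separate
run_log.json so that identical configurations produce byte-identical
manifests; the test suite and acceptance script assert that determinism.

Problem sizes in the tests and acceptance script — 25-cell spheroids for
oracle-equality checks, a 128³ fixture for the 40-iteration closing
equivalence, 200-cell spheroids for gradient and degradation statistics,
500-point hulls — were chosen as the smallest sizes at which each property
is meaningfully exercised.

## Known limitations

* One nucleus per cell; multinucleated cells break the one-to-one matching
  assumption.
* The closing runs on the voxel grid; strongly anisotropic data closes
  anisotropically in physical units (kept deliberately, see above).
* Brightfield segmentation assumes a reasonably uniform background; it
  replaces a trained pixel classifier and will underperform it on textured
  plates.
* The loose-cell percentage depends on the smoothing scale: satellites much
  smaller than σ are not recovered.
* `distance_to_hull` clamps outside-hull centroids to 0 instead of reporting
  signed distances.
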