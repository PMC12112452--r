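---
title: "Density-based safe-zone delineation for sacroiliac screws: methods and design notes"
author: "sacrozone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-based safe-zone delineation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Percutaneous sacroiliac (SI) screw fixation anchors the posterior pelvic
ring by driving a screw across the SI joint into the body of S1. The
working assumption of this package's method is biomechanical and simple:
along a mediolateral ray, the larger the integral of bone density a
trajectory traverses, the more likely a screw on that trajectory stays
intraosseous and finds purchase. The pipeline therefore reduces the 3D
planning problem to a 2D one:

1. a binary sacrum mask `M` isolates the bone of interest;
2. the masked summation projection
   `P(i,j) = Σ_k w(V[i,j,k]) · M[i,j,k] · Δs` collapses the CT volume `V`
   into a virtual lateral radiograph of the sacrum alone, in units of
   HU·mm (`w` clamps negative HU to zero);
3. the safe zone is a single connected super-level region `{P ≥ t}` at a
   high threshold `t`, reported with boundary polygon, area and centroid.

The method's assumptions are worth stating. Summed density is a proxy:
it cannot distinguish one long moderate-density column from a short very
dense one, and it ignores the third dimension of the trajectory (the
mediolateral entry angle). It presumes the mask is correct — the
projection eclipses everything outside `M`, so a mask that clips the S1
body clips the zone. And it presumes an approximately mediolateral
viewing geometry, which is why the canonical axis order (right–left,
anterior–posterior, inferior–superior) is fixed at load time and the
projection axis is explicit rather than inferred.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| isotropic target spacing | min source spacing (0.672 on the reference geometry) | mm | preserves in-plane resolution; square projection pixels |
| negative-HU clamping | on | — | air at −1000 HU would dominate full-field sums; masked sums are unaffected |
| outline quantile | 0.20 | fraction of positive masked pixels | a permissive level that traces the whole sacrum silhouette |
| zone quantile | 0.90 | fraction of positive masked pixels | "high enough to isolate only the densest region"; made reproducible as a nearest-rank quantile |
| segmentation connectivity | 26 | — | 2.976 mm slice gaps disconnect thin oblique structures under 6-connectivity |
| closing radius | 2 | mm | bridges one slice gap after thresholding |
| component selection | largest area | — | the S1 body dominates the high-density region; a seed point (mm) is available when it does not |

Quantile-based thresholds are a deliberate design choice: the technique
this package implements specifies the safe-zone threshold only
qualitatively, so the package parameterises it against the observed
density distribution of the masked projection, which transfers across
patients and phantoms without retuning. Absolute HU·mm thresholds are
accepted everywhere a quantile is.

## The phantom: what it emulates and what it does not

`phantomSpec()` encodes the study conditions for all synthetic
validation: a 96×96×40 grid at (0.672, 0.672, 2.976) mm; an ellipsoidal
sacral body (semi-axes 30, 25, 35 mm) of 150 HU trabecular bone wrapped
in a 1.0 mm cortical shell at 700 HU; an S1 core ellipsoid (15, 9, 11 mm)
at 400 HU offset 15 mm superior; two anteroposterior foraminal channels
(radius 4 mm, 20 HU) inferolateral to the core; 40 HU soft tissue; and
additive Gaussian noise (default sd 20 HU) drawn from the spec's seed, so
generation is a pure function of the spec.

The geometry was chosen once, on arithmetic grounds, to reproduce the two
regimes the method depends on:

* **Thresholding must fail.** Trabecular bone at 150 HU sits below the
  conventional +300 HU cortical threshold, so `P ≥ 300` keeps only the
  thin shell (≈10% of the body volume) and the detached core — a
  fragmented segmentation whose largest component covers a small
  fraction of the true sacrum. The freehand pathway (analytic per-slice
  traces of the body ellipse, `phantomTraces()`) recovers the body almost
  exactly; with 120 vertices per slice the inscribed-polygon deficit is
  ~0.02 mm, far below one voxel.
* **The core must dominate the projection's top decile.** A central
  mediolateral ray through the body integrates ≈60 mm × 150 HU ≈ 9·10³
  HU·mm plus ~1.1·10³ from two shell crossings; a ray through the core
  centre adds 30 mm × 250 HU ≈ 7.5·10³ on top. A tangential rim ray sees
  at most `2·sqrt(2·R·τ)` ≈ 15.5 mm of shell (R = 30 mm, shell τ = 1 mm),
  ≈ 10.8·10³ HU·mm — below the core rays. The shell is kept at 1 mm
  precisely for this separation (and a thin cortex is the clinical
  premise: low-density elderly bone); at 1.5 mm a one-pixel rim ring
  would start competing with the core in the top decile. The core
  footprint (π·9·11 ≈ 311 mm²) is ≈11% of the body silhouette
  (π·25·35 ≈ 2749 mm²), so the 0.90-quantile region and the true
  footprint are commensurate by construction, not by tuning to any
  observed run.

The phantom does **not** emulate: realistic sacral shape, the iliac wings
(the mask removes them in the real workflow anyway), partial-volume
blurring at interfaces, beam hardening, metal artefacts, or spatially
correlated noise. Tests passing on the phantom therefore demonstrate the
pipeline's internal correctness and its behaviour under the stated
density contrasts and noise — not segmentation quality on clinical
anatomy, which in the real workflow is the operator's freehand input.

## Numerical choices

* **Geometry convention.** Voxel indices are 0-based; a voxel's physical
  centre is `origin + (index + 0.5) · spacing`. Rasterisation and area
  computations are exact under this convention and every geometric test
  uses it.
* **Summation order.** The projection accumulates slices in ascending
  index order with each slice pre-multiplied by `Δs`, making the
  floating-point order identical to a plain triple loop; the oracle
  comparison in the tests is bit-for-bit, not tolerance-based.
* **Resample-then-project.** Resampling first guarantees square
  projection pixels; projecting first would entangle the anisotropy with
  the density integral. Trilinear interpolation is exact for linear
  fields (checked against a closed form); border samples clamp to the
  nearest voxel centre; binary masks resample through the 0/1 field with
  a 0.5 cut.
* **Marching squares.** Contours are extracted on the pixel-centre grid
  with linear interpolation, after padding the field with a value below
  the level so every contour closes. Interpolation fractions are clipped
  away from the nodes so centres classified inside are strictly
  enclosed. Saddle cells are resolved toward the higher-valued diagonal;
  for a super-level set that is always the inside diagonal, which makes
  contour topology agree exactly with the 8-connectivity used for
  component selection. Crossings against pad nodes pin to the pixel
  boundary so vertices never leave the image extent.
* **Nearest-rank quantile.** `pickThreshold()` returns the
  `ceiling(q·n)`-th order statistic of the positive pixels (minimum at
  q = 0, maximum at q = 1) — deterministic, interpolation-free, and
  matched by a sort-based oracle in the tests.
* **Tie-breaks.** Equal-sized connected components are resolved toward
  the component containing the lexicographically smallest index (3D:
  (i, j, k); 2D: smallest row, then column — the superior/anterior-most
  region). Degenerate inputs have defined behaviour: empty threshold
  results warn and return an empty mask (the documented failure mode
  must be observable), empty masks are rejected by consumers, a
  threshold above the projection maximum yields an empty contour set but
  a `NoRegion` error from zone delineation, and full-field projections
  are rejected by the zone delineator outright.
* **Determinism.** Phantom noise is generated from the spec seed with
  the caller's RNG state saved and restored; the pipeline derives all
  randomness from the single config seed, and the manifest records
  output MD5 hashes so reruns are verifiable.

## Design decisions on open points

* The projection integrates HU·mm rather than counting slices, so
  anisotropic and resampled inputs give consistent values.
* The sacrum outline and the safe zone use one mechanism (super-level
  contouring of the masked projection) at two levels, rather than two
  distinct procedures.
* The freehand segmentation step is represented by polygon import (CSV:
  `slice_index, polygon_id, vertex_order, x_mm, y_mm`) and rasterisation
  under the joint even-odd rule (so nested polygons cut holes); no
  interactive tracing is provided, because the method's contribution is
  downstream of how the mask is drawn.
* Masks are stored as unsigned 8-bit NIfTI; volumes as float64 NIfTI
  with an LPS-coded transform, so round-trips are exact at stored
  precision.
* DICOM input supports plain explicit-VR little-endian axial CT series
  (rescale slope/intercept applied, slices sorted by patient-space z,
  gaps checked to 1%); other transfer syntaxes and orientations are
  rejected with explicit errors rather than guessed at.
* Outline "transfer" onto the full-field radiograph is
  coordinate-identity, asserted via shared source identifiers and grid
  agreement rather than assumed.

## Problem sizes in the test suite

Unit tests run on small grids (volumes ≤ 16³ for oracle comparisons,
images ≤ 64² for contour classification, a 48×48×24 reduced phantom for
end-to-end runs); the study-scale checks use the default 96×96×40 phantom
and 20 noise realisations for safe-zone recovery. These sizes were chosen
so the brute-force oracles (triple loops, per-pixel ray casting, BFS
flood fill) remain practical while still covering every code path at the
reference acquisition geometry.

## Known limitations

* Summed density is direction-blind within the projection plane: the
  zone constrains the entry region on the lateral view, not the screw's
  inclination; the second fluoroscopic plane remains the operator's
  responsibility.
* Quantile thresholds adapt to each projection's density distribution;
  absolute HU·mm values are not comparable across scanners without
  calibration.
* The marching-squares polygon bounds member pixel centres, not pixel
  areas; reported areas are pixel-count areas (exact by definition), and
  the polygon is for display and export.
* Single-component selection assumes the dense region is contiguous at
  the chosen threshold; bimodal density patterns need the seeded
  selector.
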