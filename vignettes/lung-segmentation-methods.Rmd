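---
title: "Adaptive-threshold lung segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-threshold lung segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungseg)
```

## The problem

Breath-hold coronal 2D-MRI of the thorax is used to measure total lung volume
(TLV) at full inspiration, for example when planning motion-mitigated proton
therapy of lung tumors. An acquisition is a stack of roughly 100 coronal
slices, 512 x 512 pixels, 16-bit unsigned intensities, with in-plane spacing
0.7617 x 0.7617 mm², slices every 2.2 mm (5.5 mm thick, i.e. overlapping).
Air-filled lung is dark; surrounding tissue is bright. `lungseg` segments the
lungs in such a stack and reports the lung mask and volume in liters, fully
automatically, with no training data and no atlas.

The pipeline has four stages, run by `lung_segment()`:

1. **Preprocessing** — intensity normalization and per-plane morphological
   smoothing;
2. **Histogram analysis** — a per-plane adaptive threshold from the valleys
   of a kernel-smoothed low-intensity density, with an inter-plane
   continuity rule;
3. **2D segmentation** — binarization, removal of the zero-intensity
   periphery, and region selection gated by bilateral test strips;
4. **3D clustering** — 26-connected components, strip filtering, a
   mirror-flip test deciding one vs two lobes, and volume computation.

## Preprocessing

Raw intensities are mapped linearly from the volume's global `[min, max]` to
the working scale `[0, 255]` and rounded. The map is monotone, so it cannot
reorder histogram structure; it only fixes the scale on which all later
thresholds are expressed. A constant volume has no contrast and is rejected.

Scanner export chains differ in how raw values reach a working scale; a
volume-wise min-max map is the simplest monotone choice that lands dark lung
in the low band the threshold search expects (mode below 12 gray values),
and it is what the phantom emulates. It is a deliberate stand-in, not a
calibrated radiometric transform.

Each plane is then smoothed with grayscale **opening-by-reconstruction
followed by closing-by-reconstruction**, both with a disk of radius 12
pixels (Euclidean distance ≤ r): erode, reconstruct by dilation under the
original, dilate, then the complementary reconstruction. Reconstruction-based
(rather than plain) opening/closing is the canonical reading of the operator
sequence "erosion, reconstruction, dilation, complement": it equalizes pixel
values inside anatomical regions while *exactly* preserving the contours of
structures that survive — a structure is removed only if no part of it
survives the erosion, and anything connected to a surviving core is restored
unchanged. Two consequences matter downstream:

* the chain is idempotent (tested pixelwise), so the histogram stages see a
  stable image;
* thin dark structures *connected* to the lungs (trachea, fibrils) survive
  smoothing — which is the algorithm's characteristic artifact mechanism.

Erosion/dilation use `EBImage`; the geodesic reconstruction is a compiled
hybrid raster/queue implementation (two sweeps plus FIFO propagation),
8-connected, because no installed package provides grayscale
reconstruction. Every step is re-rounded to integer gray values so the chain
is exact integer arithmetic end to end.

## Adaptive thresholding

For each plane, pixels with intensity ≤ 32 (the search ceiling) enter a
Gaussian kernel density estimate with bandwidth 1 gray value, evaluated on a
fixed grid of step 0.25 over `[0, 32]` and renormalized to unit mass over
that support. Restricting the support keeps the bright-tissue mass from
swamping the lung mode; the ceiling of 32 and the critical intensity of 12
reflect the characteristic histogram behavior of dark-lung acquisitions on
this protocol (lung modes below 12 working-scale units, thresholds
essentially never beyond 25). Densities below 1e-9 of
the maximum are flushed to exact zero: the FFT-based KDE leaves ~1e-17
ripples in the empty tail which would otherwise spawn spurious extrema.

Local extrema are detected on the grid (strict neighbors; plateaus resolve
to their leftmost point). The **main mode** is the highest *interior* peak —
endpoint spikes are not peaks, matching `findpeaks`-style detection. This
matters in practice: the exactly-zero background outside the circular
scanner field of view produces a large spike at gray 0 which must not be
mistaken for the lung mode.

The threshold rule cascade (`select_threshold()`):

* **R1** — leftmost local minimum right of the main mode whose density is
  below one tenth of the mode's height. The "one tenth" is read as a
  constraint on the *density at* the minimum (a positional reading would be
  dimensionally inconsistent with a height).
* **R2** — if no such minimum exists: the lowest minimum between the main
  mode and the highest other interior peak beyond gray 12 (ties between
  equal peaks go left).
* **R3** — if no such secondary peak exists: the local minimum nearest the
  mode, and the plane is recorded as an **exception**. With no minima at
  all, the grid end nearer the mode is used (threshold 0 for a lung-free
  plane).

Thresholds are reported rounded to integer gray values. The module is fully
deterministic.

**Continuity**: sweeping planes in order, a threshold differing from its
predecessor's final value by more than 2 gray units is clamped to
predecessor ± 2 in the direction of the change. Clamping is the mildest
adjustment consistent with the underlying assumption that adjacent planes
have similar intensity distributions.
Planes with no pixels in the search range carry the previous threshold
forward; an empty first plane starts at 0.

## 2D segmentation and the test strips

Each plane is binarized at its threshold (strictly below). The **zero
periphery** — the 8-connected component of (near-)zero pixels touching the
image border, i.e. the area outside the circular field of view — is removed;
an epsilon is configurable for near-zero backgrounds. Remaining 8-connected
regions are inventoried and kept iff they intersect one of two **bilateral
test strips**: fixed rectangles 76 (left) and 99 (right) pixels from the
center column, 21 pixels wide, spanning 116 pixels below to 124 above the
mid row (0-based, inclusive; row 0 at top). The strips are an anatomical
prior tuned for adult 512 x 512 coronal acquisitions; they rescue lung
segments that momentarily disconnect within a plane. After periphery
removal, any remaining region is eligible regardless of border contact —
border contact alone does not disqualify (an interpretation; the
alternative would silently drop lungs clipped by the field of view).

## 3D clustering

Plane masks are stacked and labeled with 26-connectivity (the usual
volumetric default, as in Matlab-style labeling; 8-connectivity in-plane).
Components intersecting the strip prisms survive. The two
largest survivors enter the **mirror-flip lobe test**: the second is
reflected about the image mid-column (the strips are image-centered, so the
image axis, not a centroid, is the natural mirror) and accepted as the
contralateral lung iff the reflected copy overlaps the largest component by
at least half of its own size (`min_overlap_fraction = 0.5`: the cutoff sits
halfway between mirror-symmetric lungs, overlap near 1, and residuals,
overlap near 0). The result is one or two lobes; residual components are
excluded. If *nothing* intersects the
strips the pipeline raises a classed error (`lungseg_segmentation_failure`)
— failure must be loud, never an empty mask.

Volume is `voxels x 0.7617² x 2.2 mm³` (in liters): **plane separation, not
slice thickness**, because 5.5 mm slices acquired every 2.2 mm overlap, and
using thickness would count tissue 2.5 times. The trachea and protuberances
connected to the lungs are deliberately *not* removed — the algorithm cannot
distinguish them from lung, and the phantom evaluation therefore scores
against a lungs-only truth, quantifying that artifact fraction.

## Validation metrics

`dice()` is the Dice similarity coefficient on the native voxel grid.
`vfd()` is the signed volume fractional deviation
`2 (V_ref − V_auto) / (V_ref + V_auto)`. `intrafractional_deviations()`
computes, for each acquisition, the VFD of the subject mean against the
acquisition, and summarizes mean, SD, and the fraction of within-session
pairs with both members inside one SD of the cohort mean.
`session_variability()` reports, per subject, the SD of session means and
the fractional SD — the SD divided by the mean of session means, a
scale-free reproducibility measure.

## The synthetic phantom

No public data set exists for this acquisition protocol, so the package
ships a parametric thorax phantom (`phantom_spec()`, `generate_phantom()`)
that emulates the geometry: 512 x 512 x 100 voxels at the protocol
spacings, two mirror-symmetric ellipsoidal lungs (default semi-axes 50 x
105 x 85 mm, centers ±84 mm from the mid-column, ≈3.7 L total — a
plausible near-TLC volume), a bright elliptic torso, a trachea of radius
10.5 mm with a right main bronchus connecting it to the right lung
(present in the image, excluded from the ground truth, so the evaluation
quantifies the airway artifact exactly as a clinical comparison would), an
optional lung-joining bridge and an optional boundary fibril, a circular
field of view with exactly zero background outside it, an in-plane
Gaussian point spread (σ = 1.2 px) producing partial-volume intensities at
boundaries, and Rician magnitude noise (σ = 30 raw units) inside the field
of view. Gaussian noise and a noise-free mode exist for analytic checks.

Intensity model: tissue ~ N(1100, 150²) on the raw scale (spanning roughly
400–1800, the body-signal range of the emulated protocol), lung/airway signal 20 ± 5,
i.e. just above the noise floor — in T2-SSFP lung parenchyma is nearly
signal-free, and only this placement puts the lung mode below 12
working-scale units once the zero background fixes the lower end of the
min-max map. Noise is
applied only inside the field of view; the outside stays exactly zero so
the periphery decomposition is exercised as in real reconstructions.

What the phantom does *not* emulate: vascular trees and bronchial
branching beyond one bronchus, breathing motion, coil inhomogeneity,
through-plane partial volume from the 5.5 mm slab profile, and inter-plane
noise correlation. Passing the phantom cohort therefore demonstrates the
pipeline's correctness and its behavior under the documented contrast
conditions — not clinical-grade accuracy on patient data.

`generate_cohort()` emulates the repeated-measurement study design:
per-subject base volume factors uniform in ±10 %, per-acquisition volume
jitter with a chosen coefficient of variation (0.03 by default, the scale
of realistic breath-hold reproducibility), all deterministic given
one seed.

## Problem sizes used by the test suite

Unit and property tests run the standard anatomy on a coarsened raster
(128 x 128 x 25 voxels at 3.05 x 3.05 x 8.8 mm — same millimeter geometry,
1/64 the voxels) with the disk radius and strip geometry scaled by the same
factor 4. The acceptance checks run a 20-case cohort at the full
512 x 512 x 100 raster with the default configuration; `scripts/acceptance.R`
reproduces that cohort from scratch. At the coarse raster the partial-volume
band is proportionally wider, so per-case DSC is lower (≈0.88) than at full
resolution (≈0.97); tests assert accordingly.

## Numerical choices and edge cases

* Integer gray values throughout the morphology chain; KDE tail flushed
  below 1e-9 of the maximum; density grid step 0.25.
* Ties: leftmost everywhere (peaks, minima, nearest-minimum distance).
* Labeling order: components numbered by first-voxel scan order, sizes
  sorted descending with stable label tie-break — results are
  deterministic and independent of label permutation.
* Degenerate inputs: constant volumes, all-zero planes, empty masks, and
  single-plane volumes are all defined behaviors (error, threshold 0,
  empty segmentation, and a one-plane stack respectively).
* The pipeline contains no randomness; identical input and configuration
  give bit-identical results.

## Known limitations

* Connected left and right lungs are reported as one lobe; the package
  does not separate them anatomically.
* Trachea and protuberances connected to the lung are retained by design;
  volumes are overestimated by the artifact fraction unless removed
  downstream.
* The strip geometry is tuned for adult 512 x 512 coronal acquisitions and
  must be re-tuned (`strip_spec()`) for other cohorts or rasters.
* The DICOM layer reads uncompressed single-frame little-endian series
  only.
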