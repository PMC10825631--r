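# lungseg

Automated lung segmentation and total lung volume (TLV) determination for
stacks of coronal 2D magnetic resonance images acquired under breath-hold —
the setting of motion-mitigated proton therapy planning, where the goal is
to verify that the patient reaches (and reproduces) a near-total-lung-capacity
inflation state. Intended users are medical-physics and image-analysis
researchers who need a fast, deterministic, training-free lung segmentation
for dark-lung 2D-MRI protocols.

## The algorithm

For a stack of coronal planes (512 × 512 × ~100 voxels, in-plane spacing
0.7617 mm, planes every 2.2 mm):

1. **Preprocess.** Normalize intensities to a 0–255 working scale, then
   smooth each plane by grayscale opening-by-reconstruction followed by
   closing-by-reconstruction with a 12-pixel disk — plateaus inside
   anatomical regions are equalized while contours are preserved exactly.
2. **Adaptive threshold.** Per plane, build a Gaussian kernel density
   (bandwidth 1) of pixels with intensity ≤ 32 and pick the threshold by a
   rule cascade: the leftmost minimum right of the main mode with density
   below a tenth of it; else the valley between the main mode and the
   highest secondary peak beyond gray 12; else the minimum nearest the mode
   (logged as an *exception*). Thresholds of adjacent planes may differ by
   at most 2 gray values (clamped otherwise).
3. **Segment in 2D.** Binarize below the threshold, strip the zero-intensity
   periphery outside the scanner field of view, and keep the 8-connected
   regions that intersect two fixed bilateral *test strips* (an anatomical
   prior: 76/99 px from the center column, 21 px wide, −116…+124 rows around
   the mid row).
4. **Cluster in 3D.** Label 26-connected components of the stacked masks,
   keep those meeting the strip prisms, and decide one vs two lobes by
   flipping the second-largest component about the vertical mid-axis: if the
   mirror overlaps the largest by ≥ 50 % of its size it is the contralateral
   lung. The lung volume is `voxels × 0.7617² × 2.2 mm³` (plane separation,
   not slice thickness — slices overlap).

Validation metrics included: Dice similarity coefficient
`DSC = 2|A∩B| / (|A|+|B|)`, signed volume fractional deviation
`VFD = 2(V_ref − V_auto)/(V_ref + V_auto)`, intrafractional deviation
summaries and between-session (fractional) SD.

Because no public data set exists for this protocol, the package ships a
parametric synthetic thorax phantom (ellipsoidal lungs, bright torso,
trachea + bronchus excluded from the ground truth, circular field of view,
partial-volume blur, Rician noise) so the entire pipeline is testable and
reproducible without clinical data. See the methods vignette
(`vignettes/lung-segmentation-methods.Rmd`) for the full design rationale.

## Worked example

Generate a phantom at a coarsened raster (same anatomy in millimeters,
128 × 128 × 25 voxels) and segment it with the geometry scaled accordingly:

```r
library(lungseg)

spec <- phantom_spec(rows = 128L, cols = 128L, n_planes = 25L,
                     in_plane_spacing = c(3.0468, 3.0468),
                     plane_separation = 8.8, slice_thickness = 8.8, seed = 3)
ph  <- generate_phantom(spec)
cfg <- pipeline_config(preprocess = preprocess_config(disk_radius = 3),
                       strips = strip_spec(19, 25, 5, 29, 31))
res <- lung_segment(ph$volume, cfg)
summary(res)
#> Lung segmentation of phantom_seed3
#>   volume 2.983 L, 2 lobe(s), mirror overlap 0.98
#>   thresholds: min 17, median 19, max 21 gray values
#>   rules: continuity_adjusted=9, right_min_below_tenth=16
#>   exceptions: 0 plane(s)

compare_masks(res$lung_mask, ph$ground_truth, ph$volume)
#>         dsc       vfd  v_ref_L v_auto_L
#> 1 0.8860224 0.2243566 3.736515 2.982758
```

The summary reads: the two lungs were found as two mirror-symmetric 3D
components (overlap 0.98 under reflection), per-plane thresholds settled
around 19 gray values with no exception planes, and the segmented volume is
2.98 L against a 3.74 L ground truth. At this deliberately coarse raster the
partial-volume band at the lung surface is ~3 mm wide, hence DSC 0.886 and a
positive VFD (the reference is larger); at the full 512 × 512 × 100 raster
the same anatomy yields DSC ≈ 0.97 (see below). On real DICOM data the entry
point is `run_segment("dicom_dir/", pipeline_config(), output_dir = "out/")`,
which writes the mask as a DICOM series plus threshold and summary tables.

A thin command-line front end with subcommands `segment`, `evaluate`,
`phantom`, `cohort-stats` and `config-dump` ships in `inst/cli/lungseg.R`
(after installation: `system.file("cli", "lungseg.R", package = "lungseg")`).

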