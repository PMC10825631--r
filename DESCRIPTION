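Package: lungseg
Title: Adaptive-Threshold Lung Segmentation for Coronal 2D-MRI Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated lung segmentation and total lung volume determination
    for stacks of coronal 2D magnetic resonance images acquired under
    breath-hold, as used in motion-mitigated proton therapy planning. Each
    plane is smoothed by grayscale opening- and closing-by-reconstruction,
    a per-plane segmentation threshold is selected from the valleys of a
    kernel-smoothed low-intensity histogram with an inter-plane continuity
    rule, candidate regions are gated by bilateral anatomical test strips,
    and 3D connected-component analysis with a mirror-flip lobe test yields
    the final lung mask and volume in liters. Includes a minimal reader and
    writer for uncompressed single-frame DICOM series, validation metrics
    (Dice similarity coefficient, volume fractional deviation, session
    variability), and a parametric synthetic thorax phantom with known
    ground truth for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
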