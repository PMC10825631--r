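#' 3D connected components of a mask stack
#'
#' 26-connected labeling of the stacked per-plane masks. Components are
#' numbered in first-voxel scan order (deterministic) and inventoried sorted
#' by voxel count, descending, with stable ties by label.
#'
#' @param mask_stack 3D logical array `[rows, cols, planes]`.
#' @return list with `labels` (integer array, 0 = background) and
#'   `components` (data frame `label`, `voxel_count` sorted descending).
#' @export
connected_components_3d <- function(mask_stack) {
  d <- dim(mask_stack)
  stopifnot(length(d) == 3L)
  lab <- cpp_label_components(as.logical(mask_stack), as.integer(d))
  n <- attr(lab, "n_components")
  labels <- array(as.integer(lab), d)
  if (n == 0L) {
    comps <- data.frame(label = integer(0), voxel_count = integer(0))
  } else {
    counts <- tabulate(labels, nbins = n)
    comps <- data.frame(label = seq_len(n), voxel_count = counts)
    comps <- comps[order(-comps$voxel_count, comps$label), ]
    rownames(comps) <- NULL
  }
  list(labels = labels, components = comps)
}

#' Mirror-flip lobe test
#'
#' Decides whether the two largest candidate components are the two lungs.
#' The second component is mirrored about the vertical mid-axis of the image
#' (column reflection in every plane); if the mirrored copy overlaps the
#' largest component by at least `min_overlap_fraction` of its own size it
#' is accepted as the contralateral lung (two lobes), otherwise it is
#' discarded as a residual (one lobe, e.g. when both lungs are already
#' connected in one component).
#'
#' @param largest 3D logical array, largest component (nonempty).
#' @param second 3D logical array, second-largest component (may be empty).
#' @param min_overlap_fraction acceptance cutoff on
#'   `|mirror(second) & largest| / |second|`; default 0.5.
#' @return list with `n_lobes` (1 or 2) and `overlap_fraction`.
#' @export
mirror_lobe_test <- function(largest, second, min_overlap_fraction = 0.5) {
  stopifnot(identical(dim(largest), dim(second)))
  n2 <- sum(second)
  if (sum(largest) == 0L) stop("largest component is empty")
  if (n2 == 0L) return(list(n_lobes = 1L, overlap_fraction = NA_real_))
  mirrored <- second[, dim(second)[2L]:1L, , drop = FALSE]
  ov <- sum(mirrored & largest) / n2
  list(n_lobes = if (ov >= min_overlap_fraction) 2L else 1L,
       overlap_fraction = ov)
}

#' Assemble the final segmentation result
#'
#' Applies the strip-intersection filter to the 3D components (strip
#' rectangles extruded through all planes), runs the mirror-flip lobe test
#' on the two largest surviving components, and computes the lung volume
#' from the kept voxels and the acquisition geometry (in-plane pixel area
#' times plane separation). The trachea and occasional protuberances
#' connected to the lungs are deliberately not removed; they are part of the
#' algorithm's known artifact budget.
#'
#' @param cc output of [connected_components_3d()].
#' @param rect strip rectangles from [strip_rectangles()].
#' @param profile a `threshold_profile` (for the exception count).
#' @param geometry an [mri_volume()] (or list with `in_plane_spacing`,
#'   `plane_separation`) supplying voxel geometry.
#' @param min_overlap_fraction cutoff for [mirror_lobe_test()].
#' @return object of class `segmentation_result`: `lung_mask`, `components`
#'   (data frame with `label`, `voxel_count`, `intersects_strips`, `kept`),
#'   `n_lobes`, `lung_volume_L`, `threshold_profile`, `exception_count`,
#'   `mirror_overlap`.
#' @export
assemble_result <- function(cc, rect, profile, geometry,
                            min_overlap_fraction = 0.5) {
  labels <- cc$labels
  comps <- cc$components
  d <- dim(labels)
  strip2d <- .strip_mask(d[1L], d[2L], rect)
  strip_labels <- unique(labels[rep(strip2d, d[3L])])  # strips extruded through planes
  strip_labels <- strip_labels[strip_labels > 0L]
  comps$intersects_strips <- comps$label %in% strip_labels
  surv <- comps[comps$intersects_strips, , drop = FALSE]
  if (nrow(surv) == 0L)
    stop(errorCondition(
      "segmentation failure: no connected component intersects the test strips",
      class = "lungseg_segmentation_failure"))
  largest <- labels == surv$label[1L]
  if (nrow(surv) >= 2L) {
    second <- labels == surv$label[2L]
    mt <- mirror_lobe_test(largest, second, min_overlap_fraction)
  } else {
    second <- NULL
    mt <- list(n_lobes = 1L, overlap_fraction = NA_real_)
  }
  lung_mask <- largest
  kept_labels <- surv$label[1L]
  if (mt$n_lobes == 2L) {
    lung_mask <- lung_mask | second
    kept_labels <- surv$label[1:2]
  }
  comps$kept <- comps$label %in% kept_labels
  vox <- sum(lung_mask)
  vol_L <- vox * prod(geometry$in_plane_spacing) * geometry$plane_separation / 1e6
  structure(list(lung_mask = lung_mask, components = comps,
                 n_lobes = mt$n_lobes, lung_volume_L = vol_L,
                 threshold_profile = profile,
                 exception_count = sum(profile$exception),
                 mirror_overlap = mt$overlap_fraction),
            class = "segmentation_result")
}
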