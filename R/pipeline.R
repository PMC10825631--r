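#' Pipeline configuration
#'
#' Bundles the per-stage configurations. The defaults are the algorithm's
#' reference parameterization: 12-pixel disk, 0-255 working
#' scale, threshold search ceiling 32, kernel bandwidth 1, critical
#' intensity 12, maximum inter-plane jump 2, strip geometry 76/99/21/116/124
#' pixels, mirror-test overlap cutoff 0.5.
#'
#' @param preprocess a [preprocess_config()].
#' @param threshold a [threshold_config()].
#' @param strips a [strip_spec()].
#' @param min_overlap_fraction mirror-flip lobe test cutoff.
#' @param periphery_epsilon intensities at or below this count as zero for
#'   the periphery decomposition.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            threshold = threshold_config(),
                            strips = strip_spec(),
                            min_overlap_fraction = 0.5,
                            periphery_epsilon = 0) {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(threshold, "threshold_config"),
            inherits(strips, "strip_spec"))
  if (min_overlap_fraction < 0 || min_overlap_fraction > 1)
    stop("min_overlap_fraction must be in [0, 1]")
  if (periphery_epsilon < 0) stop("periphery_epsilon must be >= 0")
  structure(list(preprocess = preprocess, threshold = threshold,
                 strips = strips,
                 min_overlap_fraction = min_overlap_fraction,
                 periphery_epsilon = periphery_epsilon),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the constructors: top-level sections `preprocess`,
#' `threshold`, `strips`, and scalars `min_overlap_fraction`,
#' `periphery_epsilon`. Unknown keys raise a validation error before any
#' computation.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("preprocess", "threshold", "strips", "min_overlap_fraction",
             "periphery_epsilon")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L)
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  check_sub <- function(section, ctor) {
    given <- raw[[section]]
    if (is.null(given)) return(ctor())
    ok <- names(formals(ctor))
    bad <- setdiff(names(given), ok)
    if (length(bad) > 0L)
      stop(sprintf("unknown config key(s) in '%s': %s", section,
                   paste(bad, collapse = ", ")))
    do.call(ctor, given)
  }
  args <- list(preprocess = check_sub("preprocess", preprocess_config),
               threshold = check_sub("threshold", threshold_config),
               strips = check_sub("strips", strip_spec))
  for (k in c("min_overlap_fraction", "periphery_epsilon"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  do.call(pipeline_config, args)
}

#' Write a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  as_plain <- function(x) { x <- unclass(x); lapply(x, function(v) v) }
  yaml::write_yaml(list(preprocess = as_plain(config$preprocess),
                        threshold = as_plain(config$threshold),
                        strips = as_plain(config$strips),
                        min_overlap_fraction = config$min_overlap_fraction,
                        periphery_epsilon = config$periphery_epsilon),
                   path)
  invisible(path)
}

#' Segment the lungs in a coronal MRI volume
#'
#' Full workflow: intensity normalization and per-plane morphological
#' smoothing; kernel-density histogram analysis with the threshold rule
#' cascade and inter-plane continuity; per-plane binarization, removal of
#' the zero-intensity periphery and strip-gated region selection; 3D
#' connected-component clustering with the mirror-flip lobe test; lung
#' volume from the kept voxels and the acquisition geometry.
#'
#' A segmentation with no strip-intersecting 3D component raises a loud
#' `lungseg_segmentation_failure` error rather than returning an empty
#' mask.
#'
#' @param vol an [mri_volume()] of raw intensities.
#' @param config a [pipeline_config()].
#' @param verbose print one line per plane (threshold, rule, region count).
#' @return an object of class `lung_segmentation`; see
#'   [assemble_result()] for the fields, plus `plane_regions` (per-plane
#'   region inventories), `geometry`, and `config`.
#' @export
lung_segment <- function(vol, config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(vol, "mri_volume"), inherits(config, "pipeline_config"))
  rect <- strip_rectangles(vol$rows, vol$cols, config$strips)
  pre <- preprocess_volume(vol, config$preprocess)
  profile <- threshold_profile(pre, config$threshold)
  mask_stack <- array(FALSE, dim(pre$planes))
  plane_regions <- vector("list", vol$n_planes)
  for (p in seq_len(vol$n_planes)) {
    plane <- pre$planes[, , p]
    bin <- binarize_plane(plane, profile$threshold[p])
    bin <- remove_zero_periphery(bin, plane, config$periphery_epsilon)
    seg <- select_regions(bin, rect)
    seg$threshold_used <- profile$threshold[p]
    mask_stack[, , p] <- seg$mask
    plane_regions[[p]] <- seg$regions
    if (verbose)
      message(sprintf("plane %3d: threshold %2d rule %-22s regions %d kept %d",
                      p, profile$threshold[p], profile$rule[p],
                      nrow(seg$regions), sum(seg$regions$intersects_strip)))
  }
  cc <- connected_components_3d(mask_stack)
  res <- assemble_result(cc, rect, profile, vol,
                         min_overlap_fraction = config$min_overlap_fraction)
  res$plane_regions <- plane_regions
  res$geometry <- vol[c("in_plane_spacing", "plane_separation",
                        "slice_thickness", "rows", "cols", "n_planes")]
  res$source_id <- vol$source_id
  res$config <- config
  class(res) <- c("lung_segmentation", class(res))
  res
}

#' @export
print.lung_segmentation <- function(x, ...) {
  cat(sprintf("<lung_segmentation> %s\n", x$source_id))
  cat(sprintf("  lung volume: %.3f L in %d lobe(s)\n", x$lung_volume_L, x$n_lobes))
  cat(sprintf("  %d of %d 3D component(s) kept; %d threshold exception plane(s)\n",
              sum(x$components$kept), nrow(x$components), x$exception_count))
  invisible(x)
}

#' @export
summary.lung_segmentation <- function(object, ...) {
  thr <- object$threshold_profile$threshold
  cat(sprintf("Lung segmentation of %s\n", object$source_id))
  cat(sprintf("  volume %.3f L, %d lobe(s), mirror overlap %s\n",
              object$lung_volume_L, object$n_lobes,
              ifelse(is.na(object$mirror_overlap), "n/a",
                     sprintf("%.2f", object$mirror_overlap))))
  cat(sprintf("  thresholds: min %d, median %s, max %d gray values\n",
              min(thr), format(stats::median(thr)), max(thr)))
  rules <- table(object$threshold_profile$rule)
  cat("  rules: ", paste(sprintf("%s=%d", names(rules), rules), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  exceptions: %d plane(s)\n", object$exception_count))
  invisible(object)
}

#' Plot a lung segmentation
#'
#' Left: per-plane threshold profile colored by selection rule. Right: the
#' segmented mask of a chosen plane over the (raw) image.
#'
#' @param x a `lung_segmentation`.
#' @param vol optionally the original [mri_volume()] for the overlay panel.
#' @param plane plane index for the overlay (default: middle plane).
#' @param ... unused.
#' @export
plot.lung_segmentation <- function(x, vol = NULL, plane = NULL, ...) {
  prof <- x$threshold_profile
  op <- graphics::par(mfrow = if (is.null(vol)) c(1, 1) else c(1, 2))
  on.exit(graphics::par(op))
  cols <- c(right_min_below_tenth = "black", between_peaks_beyond_12 = "blue",
            nearest_min_exception = "red", carried_over = "gray",
            continuity_adjusted = "orange")
  graphics::plot(prof$plane, prof$threshold, type = "l", col = "gray60",
                 xlab = "plane", ylab = "threshold (gray values)",
                 main = "Per-plane thresholds")
  graphics::points(prof$plane, prof$threshold, pch = 16, cex = 0.6,
                   col = cols[prof$rule])
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   cex = 0.6, bty = "n")
  if (!is.null(vol)) {
    if (is.null(plane)) plane <- vol$n_planes %/% 2L
    img <- vol$planes[, , plane]
    graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(64),
                    axes = FALSE, main = sprintf("plane %d", plane))
    m <- x$lung_mask[, , plane]
    graphics::contour(t(m * 1)[, nrow(m):1], levels = 0.5, add = TRUE,
                      col = "red", drawlabels = FALSE)
  }
  invisible(x)
}

#' Write segmentation artifacts to a directory
#'
#' Mask DICOM series (geometry copied from `template`), the per-plane
#' threshold table, the per-plane region inventories, and a machine-readable
#' summary (volume in liters, lobe count, exception count) as tab-separated
#' text.
#'
#' @param result a `lung_segmentation`.
#' @param template the [mri_volume()] the segmentation came from.
#' @param directory output directory.
#' @param mask_high_value stored foreground value of the mask series.
#' @return the directory, invisibly.
#' @export
write_segmentation <- function(result, template, directory,
                               mask_high_value = 1L) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write_mask_series(result$lung_mask, template,
                    file.path(directory, "mask"), mask_high_value)
  write_threshold_profile(result$threshold_profile,
                          file.path(directory, "thresholds.tsv"))
  if (!is.null(result$plane_regions)) {
    reg <- do.call(rbind, lapply(seq_along(result$plane_regions), function(p) {
      r <- result$plane_regions[[p]]
      if (nrow(r) == 0L) return(NULL)
      cbind(plane = p, r)
    }))
    if (!is.null(reg))
      utils::write.table(reg, file.path(directory, "regions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary_df <- data.frame(source_id = result$source_id,
                           lung_volume_L = result$lung_volume_L,
                           n_lobes = result$n_lobes,
                           exception_count = result$exception_count,
                           n_components = nrow(result$components),
                           n_kept = sum(result$components$kept))
  utils::write.table(summary_df, file.path(directory, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(directory)
}

#' Segment a DICOM series from disk
#'
#' Thin wrapper: [read_dicom_series()], [lung_segment()],
#' [write_segmentation()].
#'
#' @param input_dir directory with the DICOM series.
#' @param config a [pipeline_config()].
#' @param output_dir where to write artifacts (optional).
#' @param verbose per-plane logging.
#' @return the `lung_segmentation`, invisibly.
#' @export
run_segment <- function(input_dir, config = pipeline_config(),
                        output_dir = NULL, verbose = FALSE) {
  vol <- read_dicom_series(input_dir)
  res <- lung_segment(vol, config, verbose = verbose)
  if (!is.null(output_dir)) write_segmentation(res, vol, output_dir)
  invisible(res)
}

#' Evaluate segmentations against reference masks
#'
#' Computes a comparison record (DSC, volume fractional deviation, volumes)
#' per case and cohort summaries: median DSC with a percentile-bootstrap
#' confidence band, and VFD summaries.
#'
#' @param records data frame of per-case comparisons as returned by
#'   [compare_masks()] (rows may be `rbind`-ed).
#' @param conf confidence level for the bootstrap band; default 0.95.
#' @param n_boot bootstrap resamples; default 10000.
#' @param seed RNG seed for the bootstrap.
#' @return list with `records`, `median_dsc`, `dsc_ci`, `median_vfd`,
#'   `vfd_ci`.
#' @export
cohort_evaluate <- function(records, conf = 0.95, n_boot = 10000L,
                            seed = 1L) {
  if (nrow(records) == 0L) stop("no comparison records to evaluate")
  set.seed(seed)
  alpha <- (1 - conf) / 2
  boot_median <- function(x) {
    reps <- vapply(seq_len(n_boot),
                   function(i) median(sample(x, replace = TRUE)), numeric(1L))
    quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  }
  list(records = records,
       median_dsc = median(records$dsc), dsc_ci = boot_median(records$dsc),
       median_vfd = median(records$vfd), vfd_ci = boot_median(records$vfd))
}
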