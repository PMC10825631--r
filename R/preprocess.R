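#' Preprocessing configuration
#'
#' Parameters of the intensity normalization and per-plane morphological
#' smoothing stage.
#'
#' @param disk_radius radius (pixels) of the disk structuring element used by
#'   the reconstruction-based opening/closing; default 12.
#' @param normalize_max upper bound of the working gray-value scale; default
#'   255. Must be at least 32 so the threshold search range fits inside the
#'   working scale.
#' @param smooth logical; apply the morphological smoothing chain (set
#'   `FALSE` for ablation experiments).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(disk_radius = 12L, normalize_max = 255L,
                              smooth = TRUE) {
  if (!is.numeric(disk_radius) || disk_radius < 1)
    stop("disk_radius must be >= 1")
  if (!is.numeric(normalize_max) || normalize_max < 32)
    stop("normalize_max must be >= 32")
  structure(list(disk_radius = as.integer(disk_radius),
                 normalize_max = as.integer(normalize_max),
                 smooth = isTRUE(smooth)),
            class = "preprocess_config")
}

# disk structuring element: pixels within Euclidean distance <= r of the center
.disk_kernel <- function(r) {
  i <- -r:r
  k <- outer(i^2, i^2, "+") <= r^2
  storage.mode(k) <- "double"
  k
}

#' Normalize a volume to the working gray-value scale
#'
#' Linear map of intensities from the volume's global `[min, max]` to
#' `[0, normalize_max]`, rounded to integers. The map is monotone, so
#' intensity order is preserved. With dark-lung acquisitions this places the
#' lung mode in the low tail of the working scale where the threshold search
#' operates.
#'
#' @param vol an [mri_volume()].
#' @param cfg a [preprocess_config()].
#' @return an [mri_volume()] with integer intensities in `0..normalize_max`.
#' @export
normalize_volume <- function(vol, cfg = preprocess_config()) {
  stopifnot(inherits(vol, "mri_volume"))
  lo <- min(vol$planes); hi <- max(vol$planes)
  if (hi <= lo)
    stop("constant-intensity volume: no contrast to segment")
  planes <- array(as.integer(round((as.numeric(vol$planes) - lo) /
                                     (hi - lo) * cfg$normalize_max)),
                  dim(vol$planes))
  out <- vol
  out$planes <- planes
  out
}

#' Morphological smoothing of one plane
#'
#' Grayscale opening-by-reconstruction followed by closing-by-reconstruction,
#' both with a disk structuring element: (1) erode; (2) reconstruct by
#' dilation with the eroded image as marker under the original; (3) dilate
#' the opened image; (4) complement, reconstruct by dilation with the
#' complemented dilation as marker under the complemented opened image, and
#' complement back. The chain flattens plateaus inside anatomical regions
#' while preserving their contours, creates no new extrema, and is
#' idempotent. Structures (bright for the opening, dark for the closing) are
#' removed only when no part of them survives the erosion; anything connected
#' to a surviving core is restored exactly by the reconstruction.
#'
#' @param plane 2D numeric matrix of normalized intensities.
#' @param cfg a [preprocess_config()]; `normalize_max` is used as the
#'   complement bound and must be >= the plane maximum.
#' @return smoothed plane, same dimensions, integer-valued.
#' @export
morph_smooth_plane <- function(plane, cfg = preprocess_config()) {
  stopifnot(is.matrix(plane))
  r <- cfg$disk_radius
  if (2L * r + 1L > nrow(plane) || 2L * r + 1L > ncol(plane))
    stop("structuring element larger than the plane")
  L <- cfg$normalize_max
  if (max(plane) > L) stop("plane exceeds normalize_max; normalize first")
  kern <- .disk_kernel(r)
  m <- matrix(as.numeric(plane), nrow(plane), ncol(plane))
  # EBImage grayscale morphology operates on the [0, 1] scale; rescale and
  # re-round so the whole chain stays exact on integer gray values
  eroded <- round(EBImage::erode(m / L, kern) * L)
  opened <- cpp_reconstruct_dilate(eroded, m)
  dil <- round(EBImage::dilate(opened / L, kern) * L)
  rec <- cpp_reconstruct_dilate(L - dil, L - opened)
  out <- L - rec
  storage.mode(out) <- "integer"
  out
}

#' Preprocess a volume (normalize, then smooth every plane)
#'
#' @param vol an [mri_volume()].
#' @param cfg a [preprocess_config()].
#' @return an [mri_volume()] on the working gray scale.
#' @export
preprocess_volume <- function(vol, cfg = preprocess_config()) {
  out <- normalize_volume(vol, cfg)
  if (cfg$smooth) {
    for (p in seq_len(out$n_planes))
      out$planes[, , p] <- morph_smooth_plane(out$planes[, , p], cfg)
  }
  out
}
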