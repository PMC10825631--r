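#' Bilateral test-strip specification
#'
#' Two fixed rectangles acting as an anatomical prior: a candidate region or
#' component must intersect one of them to count as lung. Offsets are in
#' pixels relative to the image center column and mid row; the package's
#' 0-based pixel convention applies (row 0 at the top). Defaults reproduce
#' the strip geometry tuned for 512 x 512 adult coronal acquisitions.
#'
#' @param left_inner_offset pixels between the center column and the left
#'   strip's inner edge; default 76.
#' @param right_inner_offset same for the right strip; default 99.
#' @param strip_width width of each strip in pixels; default 21.
#' @param extent_below_mid rows the strips extend below the mid row; default
#'   116.
#' @param extent_above_mid rows above the mid row; default 124.
#' @return a `strip_spec` list.
#' @export
strip_spec <- function(left_inner_offset = 76L, right_inner_offset = 99L,
                       strip_width = 21L, extent_below_mid = 116L,
                       extent_above_mid = 124L) {
  vals <- c(left_inner_offset, right_inner_offset, strip_width,
            extent_below_mid, extent_above_mid)
  if (any(!is.finite(vals)) || any(vals < 1))
    stop("all strip_spec fields must be positive integers")
  structure(list(left_inner_offset = as.integer(left_inner_offset),
                 right_inner_offset = as.integer(right_inner_offset),
                 strip_width = as.integer(strip_width),
                 extent_below_mid = as.integer(extent_below_mid),
                 extent_above_mid = as.integer(extent_above_mid)),
            class = "strip_spec")
}

#' Pixel rectangles of the bilateral test strips
#'
#' Computes the two strip rectangles for an image of `rows` x `cols` pixels.
#' With center column `c = cols %/% 2` and mid row `m = rows %/% 2`
#' (0-based), the left strip spans columns
#' `[c - left_inner_offset - strip_width, c - left_inner_offset]`, the right
#' strip `[c + right_inner_offset, c + right_inner_offset + strip_width]`,
#' and both span rows `[m - extent_above_mid, m + extent_below_mid]` (row
#' index grows downward). All bounds are inclusive and 0-based.
#'
#' @param rows,cols image dimensions in pixels.
#' @param spec a [strip_spec()].
#' @return data frame with one row per strip (`side`, `row_min`, `row_max`,
#'   `col_min`, `col_max`; 0-based inclusive).
#' @export
strip_rectangles <- function(rows, cols, spec = strip_spec()) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  cc <- cols %/% 2L
  m <- rows %/% 2L
  rect <- data.frame(
    side = c("left", "right"),
    row_min = m - spec$extent_above_mid,
    row_max = m + spec$extent_below_mid,
    col_min = c(cc - spec$left_inner_offset - spec$strip_width,
                cc + spec$right_inner_offset),
    col_max = c(cc - spec$left_inner_offset,
                cc + spec$right_inner_offset + spec$strip_width),
    stringsAsFactors = FALSE)
  for (i in 1:2) {
    if (rect$row_min[i] < 0L || rect$col_min[i] < 0L)
      stop(sprintf("%s strip extends past the image edge (row_min=%d, col_min=%d)",
                   rect$side[i], rect$row_min[i], rect$col_min[i]))
    if (rect$row_max[i] > rows - 1L || rect$col_max[i] > cols - 1L)
      stop(sprintf("%s strip extends past the image edge (row_max=%d, col_max=%d)",
                   rect$side[i], rect$row_max[i], rect$col_max[i]))
  }
  if (rect$col_max[1L] >= rect$col_min[2L])
    stop("test strips overlap")
  rect
}

# logical matrix marking strip pixels (1-based indexing internally)
.strip_mask <- function(rows, cols, rect) {
  m <- matrix(FALSE, rows, cols)
  for (i in seq_len(nrow(rect))) {
    m[(rect$row_min[i] + 1L):(rect$row_max[i] + 1L),
      (rect$col_min[i] + 1L):(rect$col_max[i] + 1L)] <- TRUE
  }
  m
}

#' Binarize a plane at a threshold
#'
#' @param plane 2D matrix of preprocessed intensities.
#' @param threshold gray value; pixels strictly below it become foreground.
#' @return logical matrix.
#' @export
binarize_plane <- function(plane, threshold) {
  plane < threshold
}

#' Remove the zero-intensity periphery from a plane mask
#'
#' The connected component (8-connectivity) of (near-)zero-intensity pixels
#' touching the image border -- the dark frame outside the scanner's field
#' of view -- is removed from the mask. Sub-threshold regions merely
#' adjacent to that component remain and are treated as ordinary candidate
#' regions.
#'
#' @param mask logical matrix from [binarize_plane()].
#' @param plane the matching intensity plane.
#' @param epsilon intensities <= `epsilon` count as zero; default 0 (exact).
#' @return the mask with the border-touching zero component removed.
#' @export
remove_zero_periphery <- function(mask, plane, epsilon = 0) {
  zero <- plane <= epsilon
  if (!any(zero)) return(mask)
  lab <- .label2d(zero)
  border_labels <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0L]
  if (length(border_labels) == 0L) return(mask)
  mask & !(matrix(lab %in% border_labels, nrow(lab), ncol(lab)))
}

# 8-connected 2D labeling via the 3D labeller with a single plane
.label2d <- function(mask) {
  d <- dim(mask)
  lab <- cpp_label_components(as.logical(mask), c(d, 1L))
  matrix(lab, d[1L], d[2L])
}

#' Label candidate regions and keep those intersecting the test strips
#'
#' 8-connected labeling of the periphery-free mask; regions are inventoried
#' (size, border contact, strip intersection) and sorted by size. A region
#' is kept iff at least one of its pixels lies inside either strip
#' rectangle; the union of kept regions forms the segmented plane mask.
#'
#' @param mask logical matrix, periphery already removed.
#' @param rect strip rectangles from [strip_rectangles()].
#' @return object of class `plane_segmentation`: `mask` (kept pixels),
#'   `regions` (data frame `label`, `pixel_count`, `touches_boundary`,
#'   `intersects_strip`, sorted by size descending), `threshold_used`
#'   (filled by the pipeline).
#' @export
select_regions <- function(mask, rect) {
  d <- dim(mask)
  lab <- .label2d(mask)
  n <- max(lab)
  if (n == 0L) {
    return(structure(list(mask = mask & FALSE,
                          regions = data.frame(label = integer(0),
                                               pixel_count = integer(0),
                                               touches_boundary = logical(0),
                                               intersects_strip = logical(0)),
                          threshold_used = NA_integer_),
                     class = "plane_segmentation"))
  }
  counts <- tabulate(lab, nbins = n)
  strip <- .strip_mask(d[1L], d[2L], rect)
  in_strip <- tabulate(lab[strip & mask], nbins = n) > 0L
  border <- unique(c(lab[1L, ], lab[d[1L], ], lab[, 1L], lab[, d[2L]]))
  touches <- seq_len(n) %in% border[border > 0L]
  regions <- data.frame(label = seq_len(n), pixel_count = counts,
                        touches_boundary = touches,
                        intersects_strip = in_strip)
  regions <- regions[order(-regions$pixel_count, regions$label), ]
  rownames(regions) <- NULL
  keep <- regions$label[regions$intersects_strip]
  out_mask <- matrix(lab %in% keep, d[1L], d[2L])
  structure(list(mask = out_mask, regions = regions,
                 threshold_used = NA_integer_),
            class = "plane_segmentation")
}
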