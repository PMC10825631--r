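#' Construct an MRI volume
#'
#' Container for an ordered stack of coronal 2D planes together with its
#' acquisition geometry. Planes are ordered along the anterior-posterior axis
#' (as given by slice-position metadata when read from DICOM). The package
#' uses a 0-based pixel coordinate convention in its documentation: row 0 at
#' the image top, column 0 at the left, plane 0 the first coronal slice;
#' internally arrays are ordinary 1-based R arrays indexed `[row, col, plane]`.
#'
#' `plane_separation` (distance between adjacent plane centers) and
#' `slice_thickness` (excited slab width) are kept as distinct fields because
#' slices may overlap (e.g. 5.5 mm thick slices every 2.2 mm); volume
#' computation uses `plane_separation` so overlapping tissue is not counted
#' twice.
#'
#' @param planes 3D numeric/integer array `[rows, cols, planes]` of
#'   non-negative intensities; a matrix is accepted for a single plane.
#' @param in_plane_spacing numeric length-2, mm per pixel (row, col).
#' @param plane_separation mm between adjacent plane centers.
#' @param slice_thickness mm slab thickness (defaults to `plane_separation`).
#' @param source_id opaque acquisition identifier.
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(planes,
                       in_plane_spacing = c(0.7617, 0.7617),
                       plane_separation = 2.2,
                       slice_thickness = plane_separation,
                       source_id = "volume") {
  if (is.matrix(planes)) planes <- array(planes, c(dim(planes), 1L))
  stopifnot(is.array(planes), length(dim(planes)) == 3L)
  d <- dim(planes)
  if (any(d < 1L)) stop("planes must have positive dimensions")
  in_plane_spacing <- rep_len(as.numeric(in_plane_spacing), 2L)
  if (any(!is.finite(in_plane_spacing)) || any(in_plane_spacing <= 0))
    stop("in_plane_spacing must be strictly positive")
  if (!is.finite(plane_separation) || plane_separation <= 0)
    stop("plane_separation must be strictly positive")
  if (!is.finite(slice_thickness) || slice_thickness <= 0)
    stop("slice_thickness must be strictly positive")
  if (min(planes, na.rm = TRUE) < 0)
    stop("intensities must be non-negative")
  structure(
    list(planes = planes,
         n_planes = d[3L], rows = d[1L], cols = d[2L],
         in_plane_spacing = in_plane_spacing,
         plane_separation = as.numeric(plane_separation),
         slice_thickness = as.numeric(slice_thickness),
         source_id = as.character(source_id)),
    class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  cat(sprintf("<mri_volume> %s\n", x$source_id))
  cat(sprintf("  %d x %d pixels, %d planes\n", x$rows, x$cols, x$n_planes))
  cat(sprintf("  spacing %.4f x %.4f mm in-plane, plane separation %.2f mm, slice thickness %.2f mm\n",
              x$in_plane_spacing[1L], x$in_plane_spacing[2L],
              x$plane_separation, x$slice_thickness))
  cat(sprintf("  intensity range [%s, %s]\n",
              format(min(x$planes)), format(max(x$planes))))
  invisible(x)
}

#' Voxel volume of an MRI volume in cubic millimeters
#'
#' Product of the in-plane pixel area and the plane separation. Uses plane
#' separation rather than slice thickness because adjacent slices may overlap.
#'
#' @param vol an `mri_volume` (or any list with `in_plane_spacing` and
#'   `plane_separation` fields).
#' @return scalar voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(vol) {
  prod(vol$in_plane_spacing) * vol$plane_separation
}
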