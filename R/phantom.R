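#' Synthetic thorax phantom specification
#'
#' Parametric description of a synthetic coronal MRI stack with known
#' ground-truth lung masks, emulating a breath-hold acquisition: two dark
#' mirror-symmetric ellipsoidal lungs inside a bright elliptical torso, a
#' dark trachea with a right main bronchus (present in the image but
#' excluded from the ground truth, so evaluation quantifies the algorithm's
#' known airway artifact), an optional thin boundary fibril, an optional
#' anterior bridge joining the lungs, a circular scanner field of view with
#' exactly-zero background outside it, an in-plane point-spread blur that
#' produces partial-volume intensities at tissue boundaries, and Rician
#' magnitude noise inside the field of view.
#'
#' Intensities are synthesized on the raw 16-bit scale of the emulated
#' protocol: body tissue spans roughly 400-1800 units while lung signal sits
#' just above the noise floor, so after min-max normalization to 0-255 the
#' lung mode falls below 12 gray values and the threshold search range 0-32
#' resolves the lung/tissue valley.
#'
#' Axes: x runs along image columns (left-right), y along rows (head-foot,
#' row 0 at top), z along planes (anterior-posterior). Offsets in mm from
#' the volume center.
#'
#' @param rows,cols,n_planes raster dimensions.
#' @param in_plane_spacing mm per pixel (row, col).
#' @param plane_separation,slice_thickness mm.
#' @param lung_semiaxes_mm ellipsoid semi-axes (x, y, z) in mm, both lungs.
#' @param lung_center_offset_mm lateral offset of each lung center from the
#'   mid-column (mirror-symmetric).
#' @param lung_center_row_mm,lung_center_plane_mm y/z offset of the lung
#'   centers.
#' @param lung_connected logical; add an anterior bridge joining the lungs
#'   (included in the ground truth), producing a single 3D component.
#' @param trachea_present logical; `trachea_radius_mm` its radius.
#' @param fibril_present logical; thin dark filament from the left lung to
#'   the torso edge.
#' @param lung_mean,lung_sd raw-scale lung (and airway) signal.
#' @param tissue_mean,tissue_sd raw-scale body tissue signal.
#' @param torso_semiaxes_mm elliptic torso cross-section semi-axes (x, y).
#' @param fov_radius_mm radius of the circular field of view; pixels outside
#'   it are exactly zero.
#' @param psf_sigma_px in-plane Gaussian point-spread sigma (pixels).
#' @param noise `"rician"` (MRI magnitude statistics), `"gaussian"`, or
#'   `"none"`; `noise_sd` its sigma on the raw scale.
#' @param seed integer RNG seed; generation is fully deterministic given the
#'   spec.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(rows = 512L, cols = 512L, n_planes = 100L,
                         in_plane_spacing = c(0.7617, 0.7617),
                         plane_separation = 2.2, slice_thickness = 5.5,
                         lung_semiaxes_mm = c(50, 105, 85),
                         lung_center_offset_mm = 84,
                         lung_center_row_mm = 0,
                         lung_center_plane_mm = 0,
                         lung_connected = FALSE,
                         trachea_present = TRUE, trachea_radius_mm = 10.5,
                         fibril_present = FALSE,
                         lung_mean = 20, lung_sd = 5,
                         tissue_mean = 1100, tissue_sd = 150,
                         torso_semiaxes_mm = c(165, 185),
                         fov_radius_mm = NULL,
                         psf_sigma_px = 1.2,
                         noise = c("rician", "gaussian", "none"),
                         noise_sd = 30, seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(fov_radius_mm))
    fov_radius_mm <- min(rows, cols) / 2 * min(in_plane_spacing)
  spec <- structure(list(
    rows = as.integer(rows), cols = as.integer(cols),
    n_planes = as.integer(n_planes),
    in_plane_spacing = rep_len(as.numeric(in_plane_spacing), 2L),
    plane_separation = plane_separation, slice_thickness = slice_thickness,
    lung_semiaxes_mm = as.numeric(lung_semiaxes_mm),
    lung_center_offset_mm = lung_center_offset_mm,
    lung_center_row_mm = lung_center_row_mm,
    lung_center_plane_mm = lung_center_plane_mm,
    lung_connected = isTRUE(lung_connected),
    trachea_present = isTRUE(trachea_present),
    trachea_radius_mm = trachea_radius_mm,
    fibril_present = isTRUE(fibril_present),
    lung_mean = lung_mean, lung_sd = lung_sd,
    tissue_mean = tissue_mean, tissue_sd = tissue_sd,
    torso_semiaxes_mm = as.numeric(torso_semiaxes_mm),
    fov_radius_mm = fov_radius_mm,
    psf_sigma_px = psf_sigma_px,
    noise = noise, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec")
  .validate_phantom_spec(spec)
  spec
}

.validate_phantom_spec <- function(s) {
  half_x <- (s$cols - 1) / 2 * s$in_plane_spacing[2L]
  half_y <- (s$rows - 1) / 2 * s$in_plane_spacing[1L]
  half_z <- (s$n_planes - 1) / 2 * s$plane_separation
  a <- s$lung_semiaxes_mm
  if (abs(s$lung_center_offset_mm) + a[1L] > min(half_x, s$fov_radius_mm) ||
      abs(s$lung_center_row_mm) + a[2L] > min(half_y, s$fov_radius_mm) ||
      abs(s$lung_center_plane_mm) + a[3L] > half_z)
    stop("lungs exceed the field of view")
  invisible(s)
}

# scale a spec's lung size so that lung volume is multiplied by volume_factor
.scale_spec <- function(spec, volume_factor, seed = spec$seed) {
  spec$lung_semiaxes_mm <- spec$lung_semiaxes_mm * volume_factor^(1 / 3)
  spec$seed <- as.integer(seed)
  .validate_phantom_spec(spec)
  spec
}

#' Generate a synthetic thorax phantom
#'
#' Voxelizes the phantom described by `spec` (see [phantom_spec()]),
#' applies the in-plane point-spread blur, zeroes everything outside the
#' circular field of view, and adds magnitude noise inside it. The
#' ground-truth mask contains the lung voxels only (plus the connecting
#' bridge when `lung_connected`); trachea and bronchus are present in the
#' image but excluded from the truth.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (an [mri_volume()] of raw integer
#'   intensities), `ground_truth` (3D logical array), `true_volume_L`
#'   (liters, from the voxelized truth), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  nr <- spec$rows; nc <- spec$cols; np <- spec$n_planes
  sy <- spec$in_plane_spacing[1L]; sx <- spec$in_plane_spacing[2L]
  x <- (seq_len(nc) - 1 - (nc - 1) / 2) * sx
  y <- (seq_len(nr) - 1 - (nr - 1) / 2) * sy
  z <- (seq_len(np) - 1 - (np - 1) / 2) * spec$plane_separation

  a <- spec$lung_semiaxes_mm
  cx <- spec$lung_center_offset_mm
  cy <- spec$lung_center_row_mm
  cz <- spec$lung_center_plane_mm
  tr <- spec$trachea_radius_mm
  apex_y <- cy - a[2L]                      # superior lung pole
  trachea_y <- c(max(min(y), apex_y - 60), apex_y + 30)
  bronchus_y <- apex_y + 25
  bronchus_r <- 8
  # bronchus must reach past the right lung's medial surface at bronchus_y
  frac <- 1 - ((bronchus_y - cy) / a[2L])^2
  bronchus_x_end <- cx - a[1L] * sqrt(max(frac, 0)) + 5
  bridge_z <- cz - a[3L] * 0.7              # anterior junction
  fibril_x <- c(-spec$torso_semiaxes_mm[1L] - 5, -cx)

  torso2d <- outer((y / spec$torso_semiaxes_mm[2L])^2,
                   (x / spec$torso_semiaxes_mm[1L])^2, "+") <= 1
  fov2d <- outer(y^2, x^2, "+") <= spec$fov_radius_mm^2
  n_fov <- sum(fov2d)

  planes <- array(0L, c(nr, nc, np))
  truth <- array(FALSE, c(nr, nc, np))
  lung_plane <- function(zz, side) {
    rem <- 1 - ((zz - cz) / a[3L])^2
    if (rem <= 0) return(NULL)
    outer(((y - cy) / a[2L])^2, ((x - side * cx) / a[1L])^2, "+") <= rem
  }
  for (p in seq_len(np)) {
    zz <- z[p]
    lungs <- matrix(FALSE, nr, nc)
    for (side in c(-1, 1)) {
      lp <- lung_plane(zz, side)
      if (!is.null(lp)) lungs <- lungs | lp
    }
    if (spec$lung_connected && abs(zz - bridge_z) <= 15) {
      lungs <- lungs | outer(abs(y - cy) <= 20, abs(x) <= cx * 0.8, "&")
    }
    dark <- lungs
    if (spec$trachea_present) {
      if (abs(zz - cz) < tr) {
        wx <- sqrt(tr^2 - (zz - cz)^2)
        dark <- dark | outer(y >= trachea_y[1L] & y <= trachea_y[2L],
                             abs(x) <= wx, "&")
      }
      if (abs(zz - cz) < bronchus_r) {
        dy <- sqrt(bronchus_r^2 - (zz - cz)^2)
        dark <- dark | outer(abs(y - bronchus_y) <= dy,
                             x >= 0 & x <= bronchus_x_end, "&")
      }
    }
    if (spec$fibril_present && abs(zz - cz) <= 1.5) {
      dark <- dark | outer(abs(y - cy) <= 1.5,
                           x >= fibril_x[1L] & x <= fibril_x[2L], "&")
    }
    signal <- matrix(0, nr, nc)
    n_t <- sum(torso2d)
    signal[torso2d] <- spec$tissue_mean + spec$tissue_sd * rnorm(n_t)
    n_d <- sum(dark)
    if (n_d > 0L)
      signal[dark] <- spec$lung_mean + spec$lung_sd * rnorm(n_d)
    signal[signal < 0] <- 0
    if (spec$psf_sigma_px > 0)
      signal <- EBImage::gblur(signal, sigma = spec$psf_sigma_px)
    signal[!fov2d] <- 0
    if (spec$noise == "rician") {
      s_fov <- signal[fov2d]
      signal[fov2d] <- sqrt((s_fov + spec$noise_sd * rnorm(n_fov))^2 +
                              (spec$noise_sd * rnorm(n_fov))^2)
    } else if (spec$noise == "gaussian") {
      signal[fov2d] <- pmax(signal[fov2d] + spec$noise_sd * rnorm(n_fov), 0)
    }
    planes[, , p] <- as.integer(round(signal))
    truth[, , p] <- lungs
  }
  vol <- mri_volume(planes, in_plane_spacing = spec$in_plane_spacing,
                    plane_separation = spec$plane_separation,
                    slice_thickness = spec$slice_thickness,
                    source_id = sprintf("phantom_seed%d", spec$seed))
  true_volume_L <- sum(truth) * voxel_volume_mm3(vol) / 1e6
  list(volume = vol, ground_truth = truth, true_volume_L = true_volume_L,
       spec = spec)
}

#' Generate a phantom cohort (subjects x sessions x repeats)
#'
#' Emulates a repeated breath-hold study: each subject gets a base lung size
#' drawn once (volume factor uniform in `1 +/- subject_jitter`), and every
#' acquisition jitters the subject's volume with coefficient of variation
#' `volume_cv` (Gaussian), emulating breath-hold reproducibility. Per-case
#' seeds are `(seed - 1) * n + 1 ... (seed - 1) * n + n` so the whole cohort
#' is deterministic given `seed`.
#'
#' @param n_subjects,sessions,repeats cohort layout (all positive).
#' @param volume_cv within-subject coefficient of variation of lung volume
#'   between acquisitions; default 0.03.
#' @param subject_jitter half-width of the uniform between-subject volume
#'   factor; default 0.10.
#' @param base_spec the [phantom_spec()] every case is scaled from.
#' @param seed cohort seed.
#' @return list with `table` (data frame: `subject`, `session`,
#'   `repetition`, `seed`, `volume_factor`, `true_volume_L` with the
#'   analytic ellipsoid volume) and `cases` (list of per-acquisition
#'   [phantom_spec()]s, to be materialized one at a time with
#'   [generate_phantom()]).
#' @export
generate_cohort <- function(n_subjects, sessions = 1L, repeats = 1L,
                            volume_cv = 0.03, subject_jitter = 0.10,
                            base_spec = phantom_spec(), seed = 1L) {
  stopifnot(n_subjects >= 1L, sessions >= 1L, repeats >= 1L)
  n <- n_subjects * sessions * repeats
  set.seed(seed)
  subj_factor <- runif(n_subjects, 1 - subject_jitter, 1 + subject_jitter)
  acq_jitter <- if (volume_cv > 0) 1 + volume_cv * rnorm(n) else rep(1, n)
  tab <- expand.grid(repetition = seq_len(repeats),
                     session = seq_len(sessions),
                     subject = seq_len(n_subjects))[, 3:1]
  tab$seed <- as.integer((seed - 1) * n + seq_len(n))
  tab$volume_factor <- subj_factor[tab$subject] * acq_jitter
  base_vol <- 2 * (4 / 3) * pi * prod(base_spec$lung_semiaxes_mm) / 1e6
  tab$true_volume_L <- base_vol * tab$volume_factor
  cases <- lapply(seq_len(n), function(i)
    .scale_spec(base_spec, tab$volume_factor[i], seed = tab$seed[i]))
  rownames(tab) <- NULL
  list(table = tab, cases = cases)
}
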