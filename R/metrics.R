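#' Dice similarity coefficient of two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; 1 for identical nonempty masks, 0 for disjoint
#' ones. Computed on the native voxel grid, no resampling.
#'
#' @param mask_a,mask_b logical arrays of equal shape; at least one nonempty.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("mask shapes differ")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0L) stop("DSC undefined: both masks empty")
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' Volume fractional deviation
#'
#' Signed relative volume difference `2 (v_a - v_b) / (v_a + v_b)`, positive
#' when the reference volume `v_a` (e.g. a manual segmentation) exceeds the
#' algorithm volume `v_b`. Antisymmetric; strictly inside `(-2, 2)` for
#' positive volumes.
#'
#' @param v_a,v_b volumes in liters (strictly positive).
#' @return signed ratio.
#' @export
vfd <- function(v_a, v_b) {
  if (any(!is.finite(c(v_a, v_b))) || any(c(v_a, v_b) <= 0))
    stop("volumes must be positive")
  2 * (v_a - v_b) / (v_a + v_b)
}

#' Intrafractional volume deviations
#'
#' For a cohort of repeated within-session volume pairs, computes the
#' fractional deviation of every acquisition from its subject's mean volume
#' (the [vfd()] of the subject mean against the acquisition), and summarizes
#' the cohort: mean and SD of the deviations, and the fraction of
#' within-session pairs whose two members both lie within one SD of the
#' cohort mean.
#'
#' @param volumes data frame with columns `subject`, `session`, `repetition`
#'   and `volume_L` (one row per acquisition; repetitions within a session
#'   form a pair).
#' @return list with `deviations` (per-acquisition data frame), `mean`,
#'   `sd`, `fraction_pairs_within_1sd`, `n_pairs`.
#' @export
intrafractional_deviations <- function(volumes) {
  stopifnot(all(c("subject", "session", "repetition", "volume_L") %in% names(volumes)))
  if (nrow(volumes) == 0L) stop("empty volume table")
  subj_mean <- tapply(volumes$volume_L, volumes$subject, mean)
  dev <- mapply(function(s, v) vfd(subj_mean[[as.character(s)]], v),
                volumes$subject, volumes$volume_L)
  out <- data.frame(subject = volumes$subject, session = volumes$session,
                    repetition = volumes$repetition,
                    volume_L = volumes$volume_L, deviation = as.numeric(dev))
  m <- mean(out$deviation); s <- stats::sd(out$deviation)
  key <- interaction(out$subject, out$session, drop = TRUE)
  within <- tapply(out$deviation, key, function(d) all(abs(d - m) <= s))
  list(deviations = out, mean = m, sd = s,
       fraction_pairs_within_1sd = mean(as.logical(within)),
       n_pairs = length(within))
}

#' Between-session variability of lung volumes
#'
#' Per subject: the mean volume of each session (over its repeats), the SD
#' across session means, and the fractional SD (SD divided by the mean of
#' the session means). Subjects with fewer than two sessions are skipped
#' with a warning.
#'
#' @param volumes data frame with columns `subject`, `session`,
#'   `repetition`, `volume_L`.
#' @return a `session_table` data frame with one row per subject:
#'   `subject`, `n_sessions`, `mean_volume_L`, `sd_of_session_means`,
#'   `fractional_sd`.
#' @export
session_variability <- function(volumes) {
  stopifnot(all(c("subject", "session", "volume_L") %in% names(volumes)))
  subjects <- unique(volumes$subject)
  rows <- lapply(subjects, function(s) {
    v <- volumes[volumes$subject == s, ]
    means <- tapply(v$volume_L, v$session, mean)
    if (length(means) < 2L) {
      warning(sprintf("subject '%s' has fewer than two sessions; skipped", s))
      return(NULL)
    }
    sdm <- stats::sd(means)
    data.frame(subject = s, n_sessions = length(means),
               mean_volume_L = mean(means), sd_of_session_means = sdm,
               fractional_sd = sdm / mean(means))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject = character(0), n_sessions = integer(0),
                      mean_volume_L = numeric(0),
                      sd_of_session_means = numeric(0),
                      fractional_sd = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("session_table", "data.frame")
  out
}

#' Compare a segmentation against a reference mask
#'
#' @param mask_auto 3D logical array, algorithm segmentation.
#' @param mask_ref 3D logical array, reference (manual or ground truth).
#' @param geometry an [mri_volume()] or list with `in_plane_spacing` and
#'   `plane_separation` (mm).
#' @return one-row data frame (`dsc`, `vfd`, `v_ref_L`, `v_auto_L`); `vfd`
#'   is reference minus algorithm, so positive when the reference is larger.
#' @export
compare_masks <- function(mask_auto, mask_ref, geometry) {
  vox_L <- prod(geometry$in_plane_spacing) * geometry$plane_separation / 1e6
  v_ref <- sum(mask_ref) * vox_L
  v_auto <- sum(mask_auto) * vox_L
  data.frame(dsc = dice(mask_ref, mask_auto), vfd = vfd(v_ref, v_auto),
             v_ref_L = v_ref, v_auto_L = v_auto)
}
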