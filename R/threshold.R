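#' Threshold-selection configuration
#'
#' Parameters of the per-plane adaptive threshold search on the low-intensity
#' histogram. All values are in working gray units (see
#' [normalize_volume()]).
#'
#' @param search_max ceiling of the threshold search range; only pixels with
#'   intensity <= `search_max` enter the density. Default 32.
#' @param bandwidth Gaussian kernel bandwidth of the density estimate.
#'   Default 1.
#' @param critical_intensity the gray value beyond which a secondary
#'   histogram peak counts as the bright side of the lung/tissue valley.
#'   Default 12.
#' @param tenth_fraction valley depth criterion: the primary rule accepts a
#'   minimum whose density is below `tenth_fraction` times the height of the
#'   global maximum. Default 0.1.
#' @param max_jump maximum allowed threshold change between adjacent planes.
#'   Default 2.
#' @param grid_step spacing of the density evaluation grid. Default 0.25;
#'   selected thresholds are reported rounded to the nearest integer gray
#'   value.
#' @return a `threshold_config` list.
#' @export
threshold_config <- function(search_max = 32, bandwidth = 1,
                             critical_intensity = 12, tenth_fraction = 0.1,
                             max_jump = 2, grid_step = 0.25) {
  vals <- c(search_max, bandwidth, critical_intensity, tenth_fraction,
            max_jump, grid_step)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all threshold_config values must be positive")
  if (critical_intensity >= search_max)
    stop("critical_intensity must be below search_max")
  structure(list(search_max = search_max, bandwidth = bandwidth,
                 critical_intensity = critical_intensity,
                 tenth_fraction = tenth_fraction, max_jump = max_jump,
                 grid_step = grid_step),
            class = "threshold_config")
}

.THRESH_RULES <- c("right_min_below_tenth", "between_peaks_beyond_12",
                   "nearest_min_exception", "carried_over",
                   "continuity_adjusted")

# local extrema on a grid; strict neighbours, plateaus resolved leftmost.
# Interior extrema are strictly greater/less than both neighbours; a grid
# endpoint that strictly exceeds its single neighbour is reported as a
# boundary peak (threshold selection ignores those, matching findpeaks-style
# peak detection, but degenerate single-mode-at-zero planes remain visible).
.grid_extrema <- function(y) {
  rl <- rle(y)
  k <- length(rl$values)
  starts <- cumsum(c(1L, rl$lengths[-k]))
  peaks <- integer(0L); mins <- integer(0L); boundary <- logical(0L)
  if (k >= 3L) {
    for (j in 2:(k - 1L)) {
      if (rl$values[j] > rl$values[j - 1L] && rl$values[j] > rl$values[j + 1L]) {
        peaks <- c(peaks, starts[j]); boundary <- c(boundary, FALSE)
      }
      if (rl$values[j] < rl$values[j - 1L] && rl$values[j] < rl$values[j + 1L])
        mins <- c(mins, starts[j])
    }
  }
  if (k >= 2L) {
    if (rl$values[1L] > rl$values[2L]) {
      peaks <- c(starts[1L], peaks); boundary <- c(TRUE, boundary)
    }
    if (rl$values[k] > rl$values[k - 1L]) {
      peaks <- c(peaks, starts[k]); boundary <- c(boundary, TRUE)
    }
  }
  list(peaks = peaks, minima = mins, boundary = boundary)
}

#' Kernel-smoothed low-intensity density of one plane
#'
#' Gaussian kernel density estimate of the plane's pixel intensities
#' restricted to `[0, search_max]`, evaluated on a fixed grid and normalized
#' to unit area over that support. Local maxima and minima of the density on
#' the grid are identified (strict neighbours; plateaus resolved to their
#' leftmost grid point).
#'
#' @param plane 2D matrix of preprocessed intensities.
#' @param cfg a [threshold_config()].
#' @return object of class `plane_density` with fields `grid`, `density`,
#'   `peaks` and `minima` (data frames with `position`, `height`), and
#'   `n_pixels` (count of contributing pixels).
#' @export
plane_density <- function(plane, cfg = threshold_config()) {
  x <- plane[plane <= cfg$search_max]
  if (length(x) == 0L)
    stop(errorCondition("no pixels at or below search_max",
                        class = "lungseg_empty_support"))
  n_grid <- round(cfg$search_max / cfg$grid_step) + 1L
  d <- stats::density(as.numeric(x), bw = cfg$bandwidth, kernel = "gaussian",
                      from = 0, to = cfg$search_max, n = n_grid)
  grid <- d$x; y <- d$y
  # flush numerical dust in the far tail to exact zero so it cannot spawn
  # spurious micro-extrema (the FFT-based KDE leaves ~1e-17 ripples there)
  y[y < 1e-9 * max(y)] <- 0
  # renormalize over the restricted support (trapezoid rule)
  area <- sum((y[-1L] + y[-length(y)]) / 2) * cfg$grid_step
  y <- y / area
  ex <- .grid_extrema(y)
  structure(list(grid = grid, density = y,
                 peaks = data.frame(position = grid[ex$peaks],
                                    height = y[ex$peaks],
                                    boundary = ex$boundary),
                 minima = data.frame(position = grid[ex$minima],
                                     height = y[ex$minima]),
                 n_pixels = length(x)),
            class = "plane_density")
}

#' Select the segmentation threshold from a plane density
#'
#' Rule cascade on the smoothed low-intensity density:
#' \describe{
#'   \item{R1 (`right_min_below_tenth`)}{Let M be the main mode: the highest
#'     interior peak of the density (a spike at the grid boundary, such as
#'     the exactly-zero background outside the scanner field of view, is not
#'     a peak). The threshold is the leftmost local minimum right of M whose
#'     density is below `tenth_fraction` times M's height.}
#'   \item{R2 (`between_peaks_beyond_12`)}{If no such minimum exists, find
#'     the highest local maximum other than M positioned right of
#'     `critical_intensity`; the threshold is the lowest local minimum
#'     between M and that peak.}
#'   \item{R3 (`nearest_min_exception`)}{If no such secondary maximum
#'     exists, the threshold is the local minimum nearest M and the plane is
#'     recorded as an exception. A density with no local minima at all
#'     resolves to the grid end nearer M.}
#' }
#' The returned threshold is rounded to the nearest integer gray value.
#'
#' @param d a [plane_density()].
#' @param cfg a [threshold_config()].
#' @return list with `threshold` (integer gray value), `rule` (one of
#'   `"right_min_below_tenth"`, `"between_peaks_beyond_12"`,
#'   `"nearest_min_exception"`), and `raw_position` (grid position before
#'   rounding).
#' @export
select_threshold <- function(d, cfg = threshold_config()) {
  y <- d$density; grid <- d$grid
  # the main mode is the highest interior peak (findpeaks semantics: a spike
  # at the grid end, e.g. the zero background outside the scanner FOV, is
  # not a peak); boundary peaks are used only when no interior peak exists
  interior <- d$peaks[!d$peaks$boundary, , drop = FALSE]
  base <- if (nrow(interior) > 0L) interior else d$peaks
  if (nrow(base) > 0L) {
    j <- which.max(base$height)    # ties: leftmost
    pos_max <- base$position[j]; h_max <- base$height[j]
  } else {
    i_max <- which.max(y)
    pos_max <- grid[i_max]; h_max <- y[i_max]
  }
  mins <- d$minima
  done <- function(pos, rule) list(threshold = as.integer(round(pos)),
                                   rule = rule, raw_position = pos)

  # R1: leftmost minimum right of the maximum, below one tenth of it
  cand <- mins[mins$position > pos_max & mins$height < cfg$tenth_fraction * h_max, ]
  if (nrow(cand) > 0L)
    return(done(cand$position[1L], "right_min_below_tenth"))

  # R2: valley between the main mode and the highest secondary interior peak
  # beyond the critical intensity
  pk <- interior[interior$position > cfg$critical_intensity &
                   interior$position != pos_max, ]
  if (nrow(pk) > 0L) {
    p2 <- pk$position[which.max(pk$height)]   # ties: leftmost via which.max
    lo <- min(pos_max, p2); hi <- max(pos_max, p2)
    between <- mins[mins$position > lo & mins$position < hi, ]
    if (nrow(between) > 0L) {
      best <- between$position[which.min(between$height)]
      return(done(best, "between_peaks_beyond_12"))
    }
    # no local minimum between the peaks (plateau edge case): lowest grid
    # point strictly between them
    sel <- which(grid > lo & grid < hi)
    if (length(sel) > 0L)
      return(done(grid[sel[which.min(y[sel])]], "between_peaks_beyond_12"))
  }

  # R3: minimum nearest the global maximum; exception
  if (nrow(mins) > 0L) {
    dist <- abs(mins$position - pos_max)
    return(done(mins$position[which.min(dist)], "nearest_min_exception"))
  }
  end <- if (pos_max <= cfg$search_max / 2) grid[1L] else grid[length(grid)]
  done(end, "nearest_min_exception")
}

#' Per-plane threshold profile of a preprocessed volume
#'
#' Runs [plane_density()] and [select_threshold()] on every plane and then
#' applies the inter-plane continuity rule via [enforce_continuity()].
#' Planes with no pixels in the search range carry the previous plane's
#' threshold forward (rule `"carried_over"`); a lung-free first plane gets
#' threshold 0.
#'
#' @param vol a preprocessed [mri_volume()].
#' @param cfg a [threshold_config()].
#' @return a `threshold_profile` data frame with columns `plane` (1-based),
#'   `raw_threshold`, `threshold`, `rule`, `exception`.
#' @export
threshold_profile <- function(vol, cfg = threshold_config()) {
  n <- vol$n_planes
  raw <- integer(n); rule <- character(n)
  prev <- 0L
  for (p in seq_len(n)) {
    res <- tryCatch({
      d <- plane_density(vol$planes[, , p], cfg)
      select_threshold(d, cfg)
    }, lungseg_empty_support = function(e) NULL)
    if (is.null(res)) {
      raw[p] <- prev           # 0 when the first plane is lung-free
      rule[p] <- "carried_over"
    } else {
      raw[p] <- res$threshold
      rule[p] <- res$rule
    }
    prev <- raw[p]
  }
  prof <- data.frame(plane = seq_len(n), raw_threshold = raw,
                     threshold = raw, rule = rule,
                     exception = rule == "nearest_min_exception",
                     stringsAsFactors = FALSE)
  class(prof) <- c("threshold_profile", "data.frame")
  enforce_continuity(prof, cfg)
}

#' Enforce inter-plane threshold continuity
#'
#' Sweeping planes in acquisition order from the second plane onward, a
#' threshold differing from the previous plane's final threshold by more
#' than `max_jump` gray units is clamped to the previous value plus
#' `max_jump` in the direction of the change, and the plane's rule becomes
#' `"continuity_adjusted"`. The first plane is never adjusted. This encodes
#' the assumption that adjacent planes have similar intensity distributions.
#'
#' @param profile a `threshold_profile` data frame (column `raw_threshold`
#'   populated in plane order).
#' @param cfg a [threshold_config()].
#' @return the profile with final `threshold`, updated `rule` and
#'   `exception` columns.
#' @export
enforce_continuity <- function(profile, cfg = threshold_config()) {
  thr <- profile$raw_threshold
  rule <- profile$rule
  n <- length(thr)
  if (n > 1L) {
    for (p in 2:n) {
      jump <- thr[p] - thr[p - 1L]
      if (abs(jump) > cfg$max_jump) {
        thr[p] <- as.integer(round(thr[p - 1L] + sign(jump) * cfg$max_jump))
        rule[p] <- "continuity_adjusted"
      }
    }
  }
  profile$threshold <- as.integer(thr)
  profile$rule <- rule
  profile$exception <- rule == "nearest_min_exception"
  profile
}

#' Write a threshold profile as a delimited text file
#'
#' @param profile a `threshold_profile`.
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_threshold_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
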