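# Independent oracles used by the property tests. These deliberately use
# different algorithms from the package internals: label propagation instead
# of stack-based flood fill, and a direct scan of grid points instead of the
# rule-cascade implementation.

# shift a 3D array by (dr, dc, dz), padding with 0
shift3 <- function(a, dr, dc, dz) {
  d <- dim(a)
  out <- array(0L, d)
  lo <- pmax(1, 1 - c(dr, dc, dz))
  hi <- pmin(d, d - c(dr, dc, dz))
  if (any(hi < lo)) return(out)
  src_r <- lo[1]:hi[1]; src_c <- lo[2]:hi[2]; src_z <- lo[3]:hi[3]
  out[src_r + dr, src_c + dc, src_z + dz] <- a[src_r, src_c, src_z]
  out
}

# connected components by iterated min-label propagation (26-connectivity;
# 8-connectivity when the third dimension is 1), relabelled in scan order of
# each component's first voxel
label_oracle <- function(mask) {
  if (length(dim(mask)) == 2L) mask <- array(mask, c(dim(mask), 1L))
  d <- dim(mask)
  lab <- array(0L, d)
  lab[mask] <- seq_len(prod(d))[mask]
  offs <- expand.grid(dr = -1:1, dc = -1:1, dz = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0 & offs$dz == 0), ]
  repeat {
    new <- lab
    for (i in seq_len(nrow(offs))) {
      sh <- shift3(lab, offs$dr[i], offs$dc[i], offs$dz[i])
      take <- mask & sh > 0L & sh < new
      new[take] <- sh[take]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  relabel_scan_order(lab)
}

# renumber labels by order of first occurrence in column-major scan order
relabel_scan_order <- function(lab) {
  v <- as.vector(lab)
  ids <- unique(v[v > 0L])
  out <- lab
  out[lab > 0L] <- match(v[v > 0L], ids)
  out
}

# threshold rule cascade evaluated by direct scan over grid points
cascade_oracle <- function(grid, y, cfg) {
  n <- length(grid)
  is_first_of_run <- c(TRUE, y[-1] != y[-n])
  prev_diff <- function(i) {      # last value before i's run differing from y[i]
    j <- i - 1L
    while (j >= 1L && y[j] == y[i]) j <- j - 1L
    if (j >= 1L) y[j] else NA_real_
  }
  next_diff <- function(i) {
    j <- i + 1L
    while (j <= n && y[j] == y[i]) j <- j + 1L
    if (j <= n) y[j] else NA_real_
  }
  peaks <- c(); mins <- c(); bpeaks <- c()
  for (i in seq_len(n)) {
    if (!is_first_of_run[i]) next
    pd <- prev_diff(i); nd <- next_diff(i)
    if (!is.na(pd) && !is.na(nd)) {
      if (y[i] > pd && y[i] > nd) peaks <- c(peaks, i)
      if (y[i] < pd && y[i] < nd) mins <- c(mins, i)
    } else if (is.na(pd) && !is.na(nd)) {
      if (y[i] > nd) bpeaks <- c(bpeaks, i)
    } else if (!is.na(pd) && is.na(nd)) {
      if (y[i] > pd) bpeaks <- c(bpeaks, i)
    }
  }
  cand <- if (length(peaks) > 0L) peaks else bpeaks
  if (length(cand) > 0L) {
    i_m <- cand[which.max(y[cand])]
  } else {
    i_m <- which.max(y)
  }
  pos_m <- grid[i_m]; h_m <- y[i_m]
  # R1
  r1 <- mins[grid[mins] > pos_m & y[mins] < cfg$tenth_fraction * h_m]
  if (length(r1) > 0L)
    return(list(threshold = as.integer(round(grid[min(r1)])),
                rule = "right_min_below_tenth"))
  # R2
  sec <- peaks[grid[peaks] > cfg$critical_intensity & grid[peaks] != pos_m]
  if (length(sec) > 0L) {
    i_p <- sec[which.max(y[sec])]
    lo <- min(pos_m, grid[i_p]); hi <- max(pos_m, grid[i_p])
    between <- mins[grid[mins] > lo & grid[mins] < hi]
    if (length(between) > 0L) {
      best <- between[which.min(y[between])]
      return(list(threshold = as.integer(round(grid[best])),
                  rule = "between_peaks_beyond_12"))
    }
    sel <- which(grid > lo & grid < hi)
    if (length(sel) > 0L)
      return(list(threshold = as.integer(round(grid[sel[which.min(y[sel])]])),
                  rule = "between_peaks_beyond_12"))
  }
  # R3
  if (length(mins) > 0L) {
    i_n <- mins[which.min(abs(grid[mins] - pos_m))]
    return(list(threshold = as.integer(round(grid[i_n])),
                rule = "nearest_min_exception"))
  }
  end <- if (pos_m <= max(grid) / 2) grid[1L] else grid[n]
  list(threshold = as.integer(round(end)), rule = "nearest_min_exception")
}

# random plane whose low-intensity histogram is a 1-3 component mixture
random_mixture_plane <- function(n_comp = sample(1:3, 1), n_pix = 1600L,
                                 search_max = 32) {
  centers <- runif(n_comp, 1, search_max - 1)
  sds <- runif(n_comp, 0.3, 4)
  w <- as.vector(stats::rmultinom(1, n_pix, runif(n_comp, 0.2, 1)))
  x <- unlist(lapply(seq_len(n_comp), function(i)
    rnorm(w[i], centers[i], sds[i])))
  x <- pmin(pmax(round(x), 0), search_max + 8)
  matrix(x, 40)
}
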