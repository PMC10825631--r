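# Minimal single-frame DICOM reader/writer (uncompressed, little endian).
# Scope: one file per coronal slice, 16-bit unsigned monochrome pixel data,
# Explicit or Implicit VR Little Endian transfer syntax. Written from the
# standard's encoding rules; no external DICOM library is involved.

.TS_IMPLICIT <- "1.2.840.10008.1.2"
.TS_EXPLICIT <- "1.2.840.10008.1.2.1"
.SOP_MR      <- "1.2.840.10008.5.1.4.1.1.4"
.UID_ROOT    <- "1.2.826.0.1.3680043.10.1405"
.LONG_VRS    <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# ---- low-level byte helpers -------------------------------------------------

.u16le <- function(raw2) {
  as.integer(raw2[1L]) + 256L * as.integer(raw2[2L])
}

.u32le <- function(raw4) {
  # double to stay exact beyond 2^31 (undefined-length sentinel 0xFFFFFFFF)
  sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))
}

.raw_u16 <- function(x) {
  x <- as.integer(x)
  writeBin(x, raw(), size = 2L, endian = "little", useBytes = TRUE)
}

.raw_u32 <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "little", useBytes = TRUE)
}

# encode one data element (explicit VR little endian)
.dcm_elem <- function(group, elem, vr, value) {
  body <- switch(vr,
    US = .raw_u16(value),
    UL = .raw_u32(value),
    OB = as.raw(value),
    OW = .raw_u16(value),
    {
      s <- charToRaw(paste(value, collapse = "\\"))
      if (length(s) %% 2L == 1L)
        s <- c(s, if (vr == "UI") as.raw(0L) else charToRaw(" "))
      s
    })
  tag <- c(.raw_u16(group), .raw_u16(elem))
  if (vr %in% .LONG_VRS) {
    c(tag, charToRaw(vr), as.raw(c(0L, 0L)), .raw_u32(length(body)), body)
  } else {
    c(tag, charToRaw(vr), .raw_u16(length(body)), body)
  }
}

.fmt_ds <- function(x) {
  vapply(x, function(v) {
    s <- formatC(v, format = "fg", digits = 10, width = 1)
    if (nchar(s) > 16L) s <- substr(s, 1L, 16L)
    s
  }, character(1L))
}

# ---- writing ----------------------------------------------------------------

.write_dicom_slice <- function(path, pixels, vol, plane_index,
                               series_uid, study_uid) {
  # pixels: integer matrix [rows, cols]; DICOM stores row-major
  rows <- nrow(pixels); cols <- ncol(pixels)
  sop_uid <- sprintf("%s.%s.%d", .UID_ROOT, series_uid_suffix(series_uid), plane_index)
  # slice position along anterior-posterior (y) axis for coronal planes
  ypos <- (plane_index - 1L) * vol$plane_separation
  meta <- c(
    .dcm_elem(0x0002L, 0x0001L, "OB", c(0L, 1L)),
    .dcm_elem(0x0002L, 0x0002L, "UI", .SOP_MR),
    .dcm_elem(0x0002L, 0x0003L, "UI", sop_uid),
    .dcm_elem(0x0002L, 0x0010L, "UI", .TS_EXPLICIT),
    .dcm_elem(0x0002L, 0x0012L, "UI", paste0(.UID_ROOT, ".1")))
  header <- c(
    raw(128L), charToRaw("DICM"),
    .dcm_elem(0x0002L, 0x0000L, "UL", length(meta)),
    meta,
    .dcm_elem(0x0008L, 0x0016L, "UI", .SOP_MR),
    .dcm_elem(0x0008L, 0x0018L, "UI", sop_uid),
    .dcm_elem(0x0008L, 0x0060L, "CS", "MR"),
    .dcm_elem(0x0018L, 0x0050L, "DS", .fmt_ds(vol$slice_thickness)),
    .dcm_elem(0x0018L, 0x0088L, "DS", .fmt_ds(vol$plane_separation)),
    .dcm_elem(0x0020L, 0x000DL, "UI", study_uid),
    .dcm_elem(0x0020L, 0x000EL, "UI", series_uid),
    .dcm_elem(0x0020L, 0x0013L, "IS", as.character(plane_index)),
    .dcm_elem(0x0020L, 0x0032L, "DS", .fmt_ds(c(0, ypos, 0))),
    # coronal orientation: image rows run head-foot (z), columns left-right (x)
    .dcm_elem(0x0020L, 0x0037L, "DS", .fmt_ds(c(1, 0, 0, 0, 0, -1))),
    .dcm_elem(0x0020L, 0x1041L, "DS", .fmt_ds(ypos)),
    .dcm_elem(0x0028L, 0x0002L, "US", 1L),
    .dcm_elem(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    .dcm_elem(0x0028L, 0x0010L, "US", rows),
    .dcm_elem(0x0028L, 0x0011L, "US", cols),
    .dcm_elem(0x0028L, 0x0030L, "DS", .fmt_ds(vol$in_plane_spacing)),
    .dcm_elem(0x0028L, 0x0100L, "US", 16L),
    .dcm_elem(0x0028L, 0x0101L, "US", 16L),
    .dcm_elem(0x0028L, 0x0102L, "US", 15L),
    .dcm_elem(0x0028L, 0x0103L, "US", 0L),
    .dcm_elem(0x7FE0L, 0x0010L, "OW", as.vector(t(pixels))))
  writeBin(header, path, useBytes = TRUE)
  invisible(path)
}

series_uid_suffix <- function(uid) {
  # short deterministic suffix so SOP instance UIDs stay within 64 chars
  sum(as.integer(charToRaw(uid))) %% 100000L
}

.series_uid_for <- function(id) {
  h <- sum(as.integer(charToRaw(as.character(id))) * seq_along(charToRaw(as.character(id)))) %% 1000000L
  sprintf("%s.%d", .UID_ROOT, h)
}

#' Write an MRI volume as a single-frame DICOM series
#'
#' One uncompressed Explicit-VR-Little-Endian file per plane, 16-bit unsigned
#' pixels, with geometry (pixel spacing, spacing between slices, slice
#' thickness, slice positions) taken from the volume. Reading the series back
#' with [read_dicom_series()] reproduces the pixel array bit-exactly.
#'
#' @param vol an [mri_volume()] with integer intensities in 0..65535.
#' @param directory output directory (created if absent).
#' @param prefix filename prefix.
#' @return the directory path, invisibly.
#' @export
write_dicom_series <- function(vol, directory, prefix = "slice") {
  stopifnot(inherits(vol, "mri_volume"))
  if (max(vol$planes) > 65535 || min(vol$planes) < 0)
    stop("intensities must fit 16-bit unsigned range")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  series_uid <- .series_uid_for(vol$source_id)
  study_uid <- paste0(.UID_ROOT, ".0")
  for (p in seq_len(vol$n_planes)) {
    f <- file.path(directory, sprintf("%s_%04d.dcm", prefix, p))
    .write_dicom_slice(f, matrix(as.integer(vol$planes[, , p]), vol$rows, vol$cols),
                       vol, p, series_uid, study_uid)
  }
  invisible(directory)
}

#' Write a binary mask volume as a DICOM series
#'
#' Writes one file per plane in the geometry of `template`. Foreground voxels
#' are stored as `high_value` (1 by default; use e.g. 4095 for viewer
#' visibility), background as 0. A read-back with [read_dicom_series()]
#' followed by `> 0` reproduces the mask bit-exactly.
#'
#' @param mask 3D logical (or 0/1) array with the template's dimensions.
#' @param template an [mri_volume()] supplying geometry.
#' @param directory output directory.
#' @param high_value stored value of foreground voxels.
#' @return the directory path, invisibly.
#' @export
write_mask_series <- function(mask, template, directory, high_value = 1L) {
  stopifnot(inherits(template, "mri_volume"))
  md <- dim(mask)
  td <- c(template$rows, template$cols, template$n_planes)
  if (length(md) != 3L || any(md != td))
    stop(sprintf("mask shape (%s) does not match template shape (%s)",
                 paste(md, collapse = "x"), paste(td, collapse = "x")))
  mv <- mri_volume(array(as.integer(mask != 0) * as.integer(high_value), md),
                   in_plane_spacing = template$in_plane_spacing,
                   plane_separation = template$plane_separation,
                   slice_thickness = template$slice_thickness,
                   source_id = paste0(template$source_id, "_mask"))
  write_dicom_series(mv, directory, prefix = "mask")
}

# ---- reading ----------------------------------------------------------------

# drop NUL padding bytes, decode, strip trailing whitespace
.raw_to_str <- function(r) {
  r <- r[r != as.raw(0L)]
  sub("\\s+$", "", rawToChar(r))
}

# parse one DICOM file; returns list of wanted fields
.read_dicom_file <- function(path) {
  n <- file.info(path)$size
  if (is.na(n) || n < 132) stop(sprintf("cannot read DICOM file '%s'", path))
  buf <- readBin(path, "raw", n)
  pos <- 1L
  if (n >= 132 && rawToChar(buf[129:132]) == "DICM") pos <- 133L
  explicit <- TRUE
  ts <- .TS_EXPLICIT
  wanted <- c("00080016", "0020000E", "0020000D", "00200032", "00200037",
              "00201041", "00200013", "00280010", "00280011", "00280030",
              "00180050", "00180088", "00280100", "00280103", "7FE00010")
  out <- list()
  in_meta <- pos == 133L
  repeat {
    if (pos + 7L > n + 1L) break
    group <- .u16le(buf[pos:(pos + 1L)])
    elem  <- .u16le(buf[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    meta_elem <- group == 0x0002L
    if (in_meta && !meta_elem) {
      in_meta <- FALSE
      explicit <- identical(ts, .TS_EXPLICIT)
      if (!ts %in% c(.TS_EXPLICIT, .TS_IMPLICIT))
        stop(sprintf("unsupported transfer syntax '%s' in '%s'", ts, path))
    }
    use_explicit <- explicit || meta_elem
    if (use_explicit) {
      vr <- rawToChar(buf[pos:(pos + 1L)])
      if (vr %in% .LONG_VRS) {
        len <- .u32le(buf[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- .u16le(buf[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- .u32le(buf[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (len == 4294967295) {
      # undefined length (sequence); skip to sequence delimitation item
      pos <- .skip_undefined(buf, pos, n)
      next
    }
    key <- sprintf("%04X%04X", group, elem)
    if (key %in% wanted) {
      val_raw <- buf[pos:(pos + len - 1L)]
      out[[key]] <- list(vr = vr, raw = val_raw)
    } else if (key == "00020010") {
      ts <- .raw_to_str(buf[pos:(pos + len - 1L)])
    }
    pos <- pos + len
    if (!is.null(out[["7FE00010"]])) break
  }
  out
}

.skip_undefined <- function(buf, pos, n) {
  depth <- 1L
  while (pos + 7L <= n + 1L && depth > 0L) {
    g <- .u16le(buf[pos:(pos + 1L)]); e <- .u16le(buf[(pos + 2L):(pos + 3L)])
    len <- .u32le(buf[(pos + 4L):(pos + 7L)])
    pos <- pos + 8L
    if (g == 0xFFFEL && e == 0xE0DDL) depth <- depth - 1L
    else if (g == 0xFFFEL && e == 0xE000L && len == 4294967295) next
    else if (len != 4294967295) pos <- pos + len
    else depth <- depth + 1L
  }
  pos
}

.dcm_str <- function(x) {
  if (is.null(x)) return(NULL)
  .raw_to_str(x$raw)
}

.dcm_ds <- function(x) {
  if (is.null(x)) return(NULL)
  as.numeric(strsplit(.dcm_str(x), "\\\\")[[1L]])
}

.dcm_us <- function(x) {
  if (is.null(x)) return(NULL)
  .u16le(x$raw[1:2])
}

#' Read a single-frame DICOM series into an MRI volume
#'
#' Reads every file in `directory` as one DICOM slice, verifies that all
#' slices belong to a single series, and stacks them ordered by slice
#' position along the stacking axis (the slice normal); filename order is
#' ignored. Geometry comes from pixel spacing, spacing between slices, and
#' slice thickness; a missing spacing-between-slices attribute falls back to
#' the median difference of slice positions.
#'
#' @param directory directory containing one DICOM file per slice.
#' @return an [mri_volume()].
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop(sprintf("no files in '%s'", directory))
  slices <- lapply(files, function(f) {
    s <- tryCatch(.read_dicom_file(f),
                  error = function(e) stop(sprintf("failed to read '%s': %s",
                                                   f, conditionMessage(e)), call. = FALSE))
    if (is.null(s[["7FE00010"]]))
      stop(sprintf("failed to read '%s': no pixel data", f), call. = FALSE)
    s
  })
  series <- vapply(slices, function(s) .dcm_str(s[["0020000E"]]) %||% "", character(1L))
  if (length(unique(series)) > 1L)
    stop(sprintf("directory contains multiple series: %s",
                 paste(unique(series), collapse = ", ")))
  rows <- vapply(slices, function(s) .dcm_us(s[["00280010"]]), integer(1L))
  cols <- vapply(slices, function(s) .dcm_us(s[["00280011"]]), integer(1L))
  if (length(unique(rows)) > 1L || length(unique(cols)) > 1L)
    stop("inconsistent plane dimensions across series")
  bits <- vapply(slices, function(s) .dcm_us(s[["00280100"]]) %||% 16L, integer(1L))
  if (any(bits != 16L)) stop("only 16-bit pixel data supported")

  pos <- vapply(slices, .slice_position, numeric(1L))
  ord <- order(pos)
  pos <- pos[ord]; slices <- slices[ord]

  nr <- rows[1L]; nc <- cols[1L]; np <- length(slices)
  planes <- array(0L, c(nr, nc, np))
  for (i in seq_len(np)) {
    px <- slices[[i]][["7FE00010"]]$raw
    v <- readBin(px, "integer", n = nr * nc, size = 2L,
                 signed = FALSE, endian = "little")
    planes[, , i] <- t(matrix(v, nrow = nc, ncol = nr))  # DICOM is row-major
  }
  sp <- .dcm_ds(slices[[1L]][["00280030"]]) %||% c(1, 1)
  sep <- .dcm_ds(slices[[1L]][["00180088"]])
  if (is.null(sep) || !is.finite(sep) || sep <= 0) {
    sep <- if (np > 1L) median(abs(diff(pos))) else 1
  }
  thick <- .dcm_ds(slices[[1L]][["00180050"]])
  if (is.null(thick) || !is.finite(thick) || thick <= 0) thick <- sep
  mri_volume(planes, in_plane_spacing = sp, plane_separation = sep,
             slice_thickness = thick,
             source_id = series[ord][1L] %||% basename(directory))
}

.slice_position <- function(s) {
  ipp <- .dcm_ds(s[["00200032"]])
  iop <- .dcm_ds(s[["00200037"]])
  if (!is.null(ipp) && length(ipp) == 3L && !is.null(iop) && length(iop) == 6L) {
    r <- iop[1:3]; c <- iop[4:6]
    normal <- c(r[2L] * c[3L] - r[3L] * c[2L],
                r[3L] * c[1L] - r[1L] * c[3L],
                r[1L] * c[2L] - r[2L] * c[1L])
    return(sum(ipp * normal))
  }
  sl <- .dcm_ds(s[["00201041"]])
  if (!is.null(sl) && length(sl) == 1L && is.finite(sl)) return(sl)
  inst <- .dcm_str(s[["00200013"]])
  if (!is.null(inst)) return(as.numeric(inst))
  stop("slice has no position metadata")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
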