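# Minimal DICOM series reader.
#
# Supports what CT export actually produces for single-frame uncompressed
# slices: part-10 files (128-byte preamble + "DICM"), explicit or implicit
# VR little endian, 16-bit pixel data, per-file rescale slope/intercept.
# Sequences with undefined length and compressed transfer syntaxes are
# rejected with a clear error rather than mis-parsed.

.TS_IMPLICIT <- "1.2.840.10008.1.2"
.TS_EXPLICIT <- "1.2.840.10008.1.2.1"

.u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
.u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

# parse one element at pos; explicit = logical
# returns list(group, elem, vr, value_raw, next_pos)
.dcm_element <- function(raw, pos, explicit) {
  group <- .u16(raw, pos)
  elem <- .u16(raw, pos + 2L)
  if (explicit) {
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- .u32(raw, pos + 8L)
      data_pos <- pos + 12L
    } else {
      len <- .u16(raw, pos + 6L)
      data_pos <- pos + 8L
    }
  } else {
    vr <- ""
    len <- .u32(raw, pos + 4L)
    data_pos <- pos + 8L
  }
  if (len == 4294967295)
    stop("input error: undefined-length DICOM element (sequence) not supported",
         call. = FALSE)
  value <- if (len > 0) raw[data_pos:(data_pos + len - 1L)] else raw(0)
  list(group = group, elem = elem, vr = vr, value = value,
       next_pos = data_pos + len)
}

.dcm_string <- function(v) trimws(rawToChar(v[v != as.raw(0)]))
.dcm_ds <- function(v) as.numeric(strsplit(.dcm_string(v), "\\\\")[[1]])
.dcm_us <- function(v) .u16(v, 1L)

# read the tags this pipeline needs from one DICOM file
.read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    return(NULL)  # not a part-10 DICOM file
  pos <- 133L
  # file meta group (0002) is always explicit VR little endian
  ts <- NULL
  while (pos + 7L <= length(raw) && .u16(raw, pos) == 2L) {
    el <- .dcm_element(raw, pos, explicit = TRUE)
    if (el$elem == 16L) ts <- .dcm_string(el$value)  # (0002,0010)
    pos <- el$next_pos
  }
  if (is.null(ts)) ts <- .TS_EXPLICIT
  if (!ts %in% c(.TS_IMPLICIT, .TS_EXPLICIT))
    stop("input error: unsupported DICOM transfer syntax ", ts,
         " in ", path, call. = FALSE)
  explicit <- ts == .TS_EXPLICIT
  tags <- list()
  while (pos + 7L <= length(raw)) {
    el <- .dcm_element(raw, pos, explicit)
    key <- sprintf("%04x,%04x", el$group, el$elem)
    tags[[key]] <- el
    pos <- el$next_pos
    if (el$group == 0x7fe0 && el$elem == 0x0010) break
  }
  g <- function(key) tags[[key]]
  need <- c("0028,0010", "0028,0011", "7fe0,0010")
  if (!all(need %in% names(tags))) return(NULL)  # image-less DICOM file
  rows <- .dcm_us(g("0028,0010")$value)
  cols <- .dcm_us(g("0028,0011")$value)
  bits <- if (!is.null(g("0028,0100"))) .dcm_us(g("0028,0100")$value) else 16L
  if (bits != 16L)
    stop("input error: only 16-bit DICOM pixel data supported (got ",
         bits, "-bit) in ", path, call. = FALSE)
  signed <- !is.null(g("0028,0103")) && .dcm_us(g("0028,0103")$value) == 1L
  slope <- if (!is.null(g("0028,1053"))) .dcm_ds(g("0028,1053")$value) else 1
  icept <- if (!is.null(g("0028,1052"))) .dcm_ds(g("0028,1052")$value) else 0
  px_spacing <- if (!is.null(g("0028,0030"))) .dcm_ds(g("0028,0030")$value)
                else c(1, 1)
  ipp <- if (!is.null(g("0020,0032"))) .dcm_ds(g("0020,0032")$value)
         else c(0, 0, 0)
  series <- if (!is.null(g("0020,000e"))) .dcm_string(g("0020,000e")$value)
            else ""
  thick <- if (!is.null(g("0018,0050"))) .dcm_ds(g("0018,0050")$value) else NA
  pd <- g("7fe0,0010")$value
  n <- rows * cols
  if (length(pd) < 2 * n)
    stop("input error: truncated pixel data in ", path, call. = FALSE)
  px <- readBin(pd, "integer", n = n, size = 2, signed = signed,
                endian = "little")
  if (!signed) px <- as.numeric(px)
  # pixel data is row-major (row by row)
  slice <- t(matrix(px, nrow = cols, ncol = rows))
  hu <- slope * slice + icept
  list(hu = hu, rows = rows, cols = cols, px_spacing = px_spacing,
       ipp = ipp, series = series, thickness = thick)
}

#' Read a DICOM CT series into a volume
#'
#' Reads every parseable single-frame DICOM file in `directory`, converts
#' stored pixel values to HU via each file's rescale slope/intercept,
#' sorts slices by spatial position along the slice axis (not by file
#' name), and assembles a [ct_volume()]. Slice spacing is the median gap
#' between consecutive slice positions; if the gaps vary by more than 10%
#' of that median a warning is issued and the median is used. In-plane
#' spacing comes from the pixel-spacing attribute.
#'
#' @param directory path containing one DICOM series.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(directory) {
  if (!dir.exists(directory))
    stop("input error: directory not found: ", directory, call. = FALSE)
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  slices <- list()
  for (f in files) {
    s <- tryCatch(.read_dicom_file(f), error = function(e) stop(e))
    if (!is.null(s)) slices[[length(slices) + 1L]] <- s
  }
  if (!length(slices))
    stop("input error: no DICOM image files found in ", directory,
         call. = FALSE)
  series <- unique(vapply(slices, `[[`, character(1), "series"))
  if (length(series) > 1)
    stop("input error: directory mixes ", length(series),
         " DICOM series", call. = FALSE)
  dims <- unique(t(vapply(slices, function(s) c(s$rows, s$cols), numeric(2))))
  if (nrow(dims) > 1)
    stop("input error: slices have inconsistent dimensions", call. = FALSE)
  z <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  nk <- length(slices)
  if (nk > 1) {
    gaps <- diff(z)
    med <- stats::median(gaps)
    if (med <= 0)
      stop("input error: duplicate or unordered slice positions", call. = FALSE)
    if (any(abs(gaps - med) > 0.1 * med))
      warning(sprintf(
        "nonuniform slice gaps (range %.3f-%.3f mm); using median %.3f mm",
        min(gaps), max(gaps), med))
    slice_sp <- med
  } else {
    slice_sp <- if (is.finite(slices[[1]]$thickness)) slices[[1]]$thickness else 1
  }
  ps <- slices[[1]]$px_spacing  # (row, col) mm
  vox <- array(0, dim = c(nk, dims[1, 1], dims[1, 2]))
  for (k in seq_len(nk)) vox[k, , ] <- slices[[k]]$hu
  ipp1 <- slices[[1]]$ipp
  ct_volume(vox, spacing = c(slice_sp, ps[1], ps[2]),
            origin = c(ipp1[3], ipp1[2], ipp1[1]),
            source_id = directory)
}
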