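# Minimal explicit-VR little-endian DICOM writer for test fixtures.
# Produces standard part-10 single-frame CT files (validated against
# pydicom in test-ct_io.R).

.raw_u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
.raw_u32 <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.dcm_pad <- function(s, pad_raw = charToRaw(" ")) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, pad_raw)
  r
}

.dcm_make_element <- function(group, elem, vr, value) {
  stopifnot(is.raw(value), length(value) %% 2 == 0)
  head <- c(.raw_u16(group), .raw_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .raw_u32(length(value)), value)
  } else {
    c(head, .raw_u16(length(value)), value)
  }
}

# write one slice; hu matrix is (rows x cols)
write_test_dicom_slice <- function(path, hu, ipp, px_spacing,
                                   series_uid, instance, slope = 1,
                                   intercept = -1024, thickness = 2) {
  stored <- round((hu - intercept) / slope)
  rows <- nrow(hu); cols <- ncol(hu)
  # pixel data row-major, int16 little endian
  v <- as.integer(t(stored))
  pd <- writeBin(v, raw(), size = 2, endian = "little")
  ds <- function(x) .dcm_pad(paste(formatC(x, format = "fg", digits = 10),
                                   collapse = "\\"))
  el <- c(
    .dcm_make_element(0x0008, 0x0060, "CS", .dcm_pad("CT")),
    .dcm_make_element(0x0018, 0x0050, "DS", ds(thickness)),
    .dcm_make_element(0x0020, 0x000e, "UI", .dcm_pad(series_uid, as.raw(0))),
    .dcm_make_element(0x0020, 0x0013, "IS", .dcm_pad(as.character(instance))),
    .dcm_make_element(0x0020, 0x0032, "DS", ds(ipp)),
    .dcm_make_element(0x0020, 0x0037, "DS", ds(c(1, 0, 0, 0, 1, 0))),
    .dcm_make_element(0x0028, 0x0002, "US", .raw_u16(1)),
    .dcm_make_element(0x0028, 0x0004, "CS", .dcm_pad("MONOCHROME2")),
    .dcm_make_element(0x0028, 0x0010, "US", .raw_u16(rows)),
    .dcm_make_element(0x0028, 0x0011, "US", .raw_u16(cols)),
    .dcm_make_element(0x0028, 0x0030, "DS", ds(px_spacing)),
    .dcm_make_element(0x0028, 0x0100, "US", .raw_u16(16)),
    .dcm_make_element(0x0028, 0x0101, "US", .raw_u16(16)),
    .dcm_make_element(0x0028, 0x0102, "US", .raw_u16(15)),
    .dcm_make_element(0x0028, 0x0103, "US", .raw_u16(1)),
    .dcm_make_element(0x0028, 0x1052, "DS", ds(intercept)),
    .dcm_make_element(0x0028, 0x1053, "DS", ds(slope)),
    .dcm_make_element(0x7fe0, 0x0010, "OW", pd)
  )
  ts <- .dcm_make_element(0x0002, 0x0010, "UI",
                          .dcm_pad("1.2.840.10008.1.2.1", as.raw(0)))
  meta <- c(.dcm_make_element(0x0002, 0x0000, "UL", .raw_u32(length(ts))), ts)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, el), con)
}

# write a whole series; voxels is (slice, row, col); returns the directory
write_test_dicom_series <- function(dir, voxels, spacing = c(2, 1, 1),
                                    origin = c(0, 0, 0),
                                    series_uid = "1.2.826.0.1.999999.1",
                                    slope = 1, intercept = -1024,
                                    file_names = NULL, z_positions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nk <- dim(voxels)[1]
  if (is.null(file_names))
    file_names <- sprintf("slice_%03d.dcm", seq_len(nk))
  if (is.null(z_positions))
    z_positions <- origin[1] + (seq_len(nk) - 1) * spacing[1]
  for (k in seq_len(nk)) {
    write_test_dicom_slice(
      file.path(dir, file_names[k]), voxels[k, , ],
      ipp = c(origin[3], origin[2], z_positions[k]),
      px_spacing = c(spacing[2], spacing[3]),
      series_uid = series_uid, instance = k,
      slope = slope, intercept = intercept, thickness = spacing[1])
  }
  dir
}
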