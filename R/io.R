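# Volume and candidate-list I/O.
#
# NIfTI goes through RNifti; MetaImage (.mhd + .raw, or single-file .mha)
# is read and written directly — the format is a plain-text header plus a
# raw little-endian block. On disk both formats store axes (x, y, z)
# fastest-first; in memory the package uses (slice, row, col) = (z, y, x),
# so arrays are permuted on the way in and out.

.SUPPORTED_EXT <- c(".nii", ".nii.gz", ".mhd", ".mha")

.file_ext <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii\\.gz$", p)) return(".nii.gz")
  if (grepl("\\.nii$", p)) return(".nii")
  if (grepl("\\.mhd$", p)) return(".mhd")
  if (grepl("\\.mha$", p)) return(".mha")
  ""
}

#' Read a CT volume from a single-file format
#'
#' Reads NIfTI (`.nii`, `.nii.gz`) or MetaImage (`.mhd`, `.mha`) volumes
#' into a [ct_volume()], with HU clamping applied. The file must have
#' exactly 3 spatial dimensions.
#'
#' @param path path to the volume file.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("input error: file not found: ", path, call. = FALSE)
  ext <- .file_ext(path)
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) != 3L)
      stop("input error: expected a 3D volume, got ",
           length(dim(a)), "D: ", path, call. = FALSE)
    sp_xyz <- RNifti::pixdim(img)
    xf <- RNifti::xform(img)
    org_xyz <- xf[1:3, 4]
    ct_volume(aperm(a, c(3, 2, 1)), spacing = rev(sp_xyz),
              origin = rev(org_xyz), source_id = path)
  } else if (ext %in% c(".mhd", ".mha")) {
    .read_metaimage(path)
  } else {
    stop("input error: unsupported extension for ", path,
         " (supported: ", paste(.SUPPORTED_EXT, collapse = ", "), ")",
         call. = FALSE)
  }
}

#' Write a CT volume or binary mask
#'
#' Writes NIfTI or MetaImage, dialect inferred from the extension. HU
#' volumes are stored as 16-bit integers (lossless for CT's integer HU
#' scale after rounding); masks as 8-bit. Spacing and origin round-trip.
#'
#' @param x a [ct_volume()] or [binary_mask()].
#' @param path output path ending in `.nii`, `.nii.gz`, `.mhd` or `.mha`.
#' @export
write_volume <- function(x, path) {
  is_mask <- inherits(x, "binary_mask")
  if (!is_mask && !inherits(x, "ct_volume"))
    stop("x must be a ct_volume or binary_mask", call. = FALSE)
  vox <- if (is_mask) x$values else round(x$voxels)
  ext <- .file_ext(path)
  if (ext %in% c(".nii", ".nii.gz")) {
    a <- aperm(vox, c(3, 2, 1))
    storage.mode(a) <- "integer"
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- rev(x$spacing)
    m <- diag(c(rev(x$spacing), 1))
    m[1:3, 4] <- rev(x$origin)
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "int16")
  } else if (ext %in% c(".mhd", ".mha")) {
    .write_metaimage(vox, x$spacing, x$origin, path,
                     type = if (is_mask) "MET_UCHAR" else "MET_SHORT")
  } else {
    stop("input error: unsupported extension for ", path,
         " (supported: ", paste(.SUPPORTED_EXT, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(path)
}

.MET_TYPES <- list(MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
                   MET_CHAR = list(what = "integer", size = 1, signed = TRUE),
                   MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
                   MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
                   MET_INT = list(what = "integer", size = 4, signed = TRUE),
                   MET_FLOAT = list(what = "numeric", size = 4, signed = TRUE),
                   MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE))

.write_metaimage <- function(vox, spacing, origin, path, type = "MET_SHORT") {
  d <- dim(vox)
  single_file <- .file_ext(path) == ".mha"
  data_file <- if (single_file) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[3], d[2], d[1]),
    sprintf("ElementSpacing = %g %g %g", spacing[3], spacing[2], spacing[1]),
    sprintf("Offset = %g %g %g", origin[3], origin[2], origin[1]),
    sprintf("ElementType = %s", type),
    sprintf("ElementDataFile = %s", data_file)
  )
  tinfo <- .MET_TYPES[[type]]
  a <- as.vector(aperm(vox, c(3, 2, 1)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (single_file) {
    if (tinfo$what == "integer")
      writeBin(as.integer(a), con, size = tinfo$size, endian = "little")
    else
      writeBin(as.numeric(a), con, size = tinfo$size, endian = "little")
  }
  if (!single_file) {
    rcon <- file(file.path(dirname(path), data_file), "wb")
    if (tinfo$what == "integer")
      writeBin(as.integer(a), rcon, size = tinfo$size, endian = "little")
    else
      writeBin(as.numeric(a), rcon, size = tinfo$size, endian = "little")
    close(rcon)
  }
  invisible(path)
}

.read_metaimage <- function(path) {
  # header: text lines "Key = Value" until ElementDataFile
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  hdr <- list()
  pos <- 1L
  repeat {
    nl <- which(raw_all[pos:length(raw_all)] == as.raw(10))[1]
    if (is.na(nl)) stop("input error: malformed MetaImage header: ", path,
                        call. = FALSE)
    line <- rawToChar(raw_all[pos:(pos + nl - 2L)])
    line <- sub("\r$", "", line)
    pos <- pos + nl
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) hdr[[kv[2]]] <- trimws(kv[3])
    if (!is.na(kv[2]) && length(kv) == 3 && kv[2] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "0")
  if (ndims != 3L)
    stop("input error: expected a 3D volume, got ", ndims, "D: ", path,
         call. = FALSE)
  d_xyz <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp_xyz <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  org_xyz <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  type <- hdr$ElementType %||% "MET_SHORT"
  tinfo <- .MET_TYPES[[type]]
  if (is.null(tinfo))
    stop("input error: unsupported MetaImage ElementType ", type, call. = FALSE)
  if (!is.null(hdr$CompressedData) && tolower(hdr$CompressedData) == "true")
    stop("input error: compressed MetaImage not supported: ", path,
         call. = FALSE)
  n <- prod(d_xyz)
  if (hdr$ElementDataFile == "LOCAL") {
    data_raw <- raw_all[pos:length(raw_all)]
    a <- readBin(data_raw, tinfo$what, n = n, size = tinfo$size,
                 signed = tinfo$signed, endian = "little")
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path))
      stop("input error: raw data file not found: ", raw_path, call. = FALSE)
    a <- readBin(raw_path, tinfo$what, n = n, size = tinfo$size,
                 signed = tinfo$signed, endian = "little")
  }
  if (length(a) < n)
    stop("input error: truncated MetaImage data: ", path, call. = FALSE)
  vox <- aperm(array(a, dim = d_xyz), c(3, 2, 1))
  ct_volume(vox, spacing = rev(sp_xyz), origin = rev(org_xyz),
            source_id = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.CAND_COLS <- c("id", "k", "i", "j", "x_mm", "y_mm", "z_mm", "radius_mm",
                "response", "label", "score")

#' Write / read a candidate list as CSV
#'
#' One record per candidate with 1-based voxel indices `(k, i, j)`, world
#' mm coordinates, radius estimate, filter response, class label and
#' score. Columns: `id, k, i, j, x_mm, y_mm, z_mm, radius_mm, response,
#' label, score`. Reading the file back yields an equal candidate frame.
#' Candidates with non-finite responses are refused.
#'
#' @param candidates candidate data frame (see [detect_candidates()]).
#' @param path CSV path.
#' @export
write_candidates <- function(candidates, path) {
  df <- as.data.frame(candidates)
  if (nrow(df) && any(!is.finite(df$response)))
    stop("validation error: candidate responses must be finite",
         call. = FALSE)
  out <- data.frame(id = seq_len(nrow(df)),
                    k = df$k, i = df$i, j = df$j,
                    x_mm = df$x_mm, y_mm = df$y_mm, z_mm = df$z_mm,
                    radius_mm = df$radius_mm, response = df$response,
                    label = if ("label" %in% names(df)) df$label else NA,
                    score = if ("score" %in% names(df)) df$score else NA)
  if (!nrow(df))
    out <- out[0, ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  if (!file.exists(path))
    stop("input error: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(label = "character"))
  df$id <- NULL
  df[, c("k", "i", "j", "z_mm", "y_mm", "x_mm", "radius_mm", "response",
         "label", "score")]
}
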