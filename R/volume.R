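#' CT volume container
#'
#' A `ct_volume` holds a 3D scalar grid of Hounsfield units (HU) together
#' with its physical geometry. The index order is `(slice, row, column)` =
#' `(z, y, x)`, so `voxels[k, i, j]` is slice `k`, image row `i`, image
#' column `j`. World coordinates (mm) of voxel `(k, i, j)` are
#' `origin + (k - 1, i - 1, j - 1) * spacing`.
#'
#' HU values are clamped to the 12-bit CT range \[-1024, 3071\] on
#' construction; non-finite voxels are rejected.
#'
#' @param voxels 3D numeric array of HU values, index order (slice, row, col).
#' @param spacing numeric length-3, mm per axis `(slice, row, col)`; all > 0.
#' @param origin numeric length-3, world mm position of voxel `(1, 1, 1)`.
#' @param source_id free-text provenance tag.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      source_id = "unknown") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array", call. = FALSE)
  if (!all(is.finite(voxels)))
    stop("voxels must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)", call. = FALSE)
  storage.mode(voxels) <- "double"
  voxels[] <- pmin(pmax(voxels, -1024), 3071)
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         source_id = as.character(source_id)[1]),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels (slice x row x col)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing : %.3f x %.3f x %.3f mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin  : (%.1f, %.1f, %.1f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  HU range: [%d, %d]   source: %s\n",
              round(min(x$voxels)), round(max(x$voxels)), x$source_id))
  invisible(x)
}

#' Binary mask on a CT grid
#'
#' Indicator array on the same `(slice, row, col)` grid as a parent
#' [ct_volume()]. Carries the parent's spacing and origin so masks can be
#' written to disk and measured in physical units on their own.
#'
#' @param values 3D array with values in \{0, 1\} (logical accepted).
#' @param spacing,origin geometry of the parent grid (mm).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("mask values must be a 3D array", call. = FALSE)
  if (is.logical(values)) {
    v <- array(as.integer(values), dim = dim(values))
  } else {
    if (!all(values %in% c(0, 1)))
      stop("mask values must be 0/1", call. = FALSE)
    v <- array(as.integer(values), dim = dim(values))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)", call. = FALSE)
  structure(
    list(values = v, parent_shape = dim(v), spacing = spacing,
         origin = as.numeric(origin)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- x$parent_shape
  cat(sprintf("<binary_mask> %d x %d x %d, %d foreground voxels (%.1f ml)\n",
              d[1], d[2], d[3], sum(x$values),
              sum(x$values) * prod(x$spacing) / 1000))
  invisible(x)
}

#' Convert voxel indices to world coordinates
#'
#' @param geom a `ct_volume` or `binary_mask` (anything with `spacing` and
#'   `origin`).
#' @param index numeric matrix (n x 3) or length-3 vector of 1-based
#'   `(slice, row, col)` indices (fractional allowed, e.g. centroids).
#' @return n x 3 matrix of world mm coordinates in `(z, y, x)` order.
#' @export
index_to_mm <- function(geom, index) {
  idx <- if (is.matrix(index)) index else matrix(index, ncol = 3)
  sweep(sweep(idx - 1, 2, geom$spacing, "*"), 2, geom$origin, "+")
}

#' Convert world coordinates to voxel indices
#'
#' Inverse of [index_to_mm()]; returns fractional 1-based indices.
#'
#' @inheritParams index_to_mm
#' @param mm n x 3 matrix or length-3 vector of world mm `(z, y, x)`.
#' @export
mm_to_index <- function(geom, mm) {
  m <- if (is.matrix(mm)) mm else matrix(mm, ncol = 3)
  sweep(sweep(m, 2, geom$origin, "-"), 2, geom$spacing, "/") + 1
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A n B| / (|A| + |B|)`; 1 for identical masks, and defined as 1 when
#' both masks are empty.
#'
#' @param a,b `binary_mask` objects (or 0/1 arrays) on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  av <- if (inherits(a, "binary_mask")) a$values else a
  bv <- if (inherits(b, "binary_mask")) b$values else b
  if (!identical(dim(av), dim(bv)))
    stop("masks must share one grid", call. = FALSE)
  s <- sum(av) + sum(bv)
  if (s == 0) return(1)
  2 * sum(av * bv) / s
}

# internal: coerce mask-or-array to integer array
.mask_values <- function(m) {
  if (inherits(m, "binary_mask")) m$values else m
}
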