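#' Iterative optimal (isodata) threshold
#'
#' Finds the threshold separating low-attenuation (air/lung) from
#' soft-tissue voxels by the classical isodata fixed-point iteration:
#' starting from the volume's mid-range, the threshold is repeatedly
#' replaced by the mean of the two class means,
#' `T <- (mean(v < T) + mean(v >= T)) / 2`, until it moves by at most
#' `tolerance` HU.
#'
#' @param volume a [ct_volume()] (or bare numeric array of HU).
#' @param tolerance convergence tolerance in HU.
#' @param max_iter maximum number of iterations.
#' @return A `threshold_result`: list with `threshold` (HU), `iterations`,
#'   and `class_means` (mean below, mean above).
#' @export
optimal_threshold <- function(volume, tolerance = 0.5, max_iter = 100L) {
  v <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  v <- as.numeric(v)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("degenerate input: volume is constant, no threshold exists",
         call. = FALSE)
  t_cur <- mean(rng)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lo <- v < t_cur
    m_lo <- mean(v[lo])
    m_hi <- mean(v[!lo])
    # guard: all mass on one side of the mid-range start
    if (!is.finite(m_lo)) m_lo <- rng[1]
    if (!is.finite(m_hi)) m_hi <- rng[2]
    t_new <- (m_lo + m_hi) / 2
    if (abs(t_new - t_cur) <= tolerance) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
    if (iter >= max_iter)
      stop(sprintf(
        "optimal_threshold did not converge in %d iterations (last threshold %.2f HU)",
        max_iter, t_cur), call. = FALSE)
  }
  lo <- v < t_cur
  structure(
    list(threshold = t_cur, iterations = iter,
         class_means = c(below = mean(v[lo]), above = mean(v[!lo]))),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> %.1f HU after %d iterations (class means %.1f / %.1f)\n",
    x$threshold, x$iterations, x$class_means[1], x$class_means[2]))
  invisible(x)
}

#' Extract the lung fields from a thresholded CT volume
#'
#' Voxels below the threshold are "air". Air connected (by faces, in 3D) to
#' the volume border is ambient air and is removed; with
#' `remove_airway = FALSE` (the default), components touching only the top
#' face (slice 1) are kept, which retains a trachea entering from above.
#' Of the remaining components, the largest `keep_components` whose volume
#' exceeds `min_volume_ml` are kept.
#'
#' Ambient air is identified by connection to the in-plane (row/column)
#' border faces — the slice axis is excluded because clinical acquisitions
#' are routinely cropped in that direction and the lung may reach the
#' first or last slice. With `remove_airway = TRUE`, components connected
#' to top-face (slice 1) air — the trachea entering from above — are
#' removed as well.
#'
#' @param volume a [ct_volume()].
#' @param threshold a `threshold_result` from [optimal_threshold()] or a
#'   bare HU number.
#' @param min_volume_ml minimum component volume (ml) to count as lung.
#'   400 ml suits clinical scans; desk-scale phantoms need less (see
#'   [phantom_config()]).
#' @param keep_components keep at most this many components (2 lungs; 1 if
#'   they merge across the anterior junction).
#' @param remove_airway if `TRUE`, components connected to top-face air
#'   (trachea entry) are removed as well.
#' @return A [binary_mask()]: the unrepaired lung mask.
#' @export
extract_lung_mask <- function(volume, threshold, min_volume_ml = 400,
                              keep_components = 2L, remove_airway = FALSE) {
  thr <- if (inherits(threshold, "threshold_result")) threshold$threshold
         else as.numeric(threshold)
  air <- volume$voxels < thr
  lab <- label_components(air, "face3d")
  if (max(lab) == 0L)
    stop("segmentation failure: no air voxels below threshold", call. = FALSE)
  drop <- .border_labels(lab, "side")
  if (remove_airway)
    drop <- union(drop, .border_labels(lab, "top"))
  lab[lab %in% drop] <- 0L
  sizes <- .component_sizes(lab)
  vox_ml <- prod(volume$spacing) / 1000
  big <- which(sizes * vox_ml > min_volume_ml)
  if (!length(big))
    stop(sprintf(
      "segmentation failure: no candidate lung component exceeds %.0f ml",
      min_volume_ml), call. = FALSE)
  keep <- big[order(sizes[big], decreasing = TRUE)]
  keep <- keep[seq_len(min(length(keep), keep_components))]
  binary_mask(array(lab %in% keep, dim = dim(lab)),
              spacing = volume$spacing, origin = volume$origin)
}

#' Fill interior cavities of a mask, slice by slice
#'
#' In each slice, background components (4-connectivity) not connected to
#' the slice border become foreground. This recovers dense structures
#' (vessels, calcified or solid nodules) that thresholding excluded from
#' the lung field. Extensive (`output >= input`) and idempotent.
#'
#' @param mask a [binary_mask()].
#' @return A [binary_mask()] with per-slice holes filled.
#' @export
fill_cavities <- function(mask) {
  v <- mask$values
  d <- dim(v)
  out <- v
  for (k in seq_len(d[1])) {
    sl <- v[k, , ]
    if (!any(sl == 1L)) next
    bg <- sl == 0L
    if (!any(bg)) next
    lab <- label_components(bg, "plane4")
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border <- border[border > 0L]
    hole <- bg & !(lab %in% border)
    sl[hole] <- 1L
    out[k, , ] <- sl
  }
  binary_mask(out, spacing = mask$spacing, origin = mask$origin)
}

#' Repair the lung contour by per-slice morphological closing
#'
#' Bridges pleural indentations of radius up to `ball_radius_mm` — such as
#' the notch left where a juxtapleural nodule was excluded by
#' thresholding. Each slice's connected components (4-connectivity) are
#' closed independently with a disk structuring element on a
#' zero-padded canvas, so separate structures (the two lungs) are never
#' fused and image-border clipping cannot distort the result. The
#' structuring radius is derived from rolling-ball geometry: a disk of
#' radius `R` dips by about `a^2 / (2R)` into a hemispherical notch of
#' radius `a`, so `R ~ 1.4 a^2` (pixels) keeps the residual dip under half
#' a pixel and the notch is bridged completely, while convex boundaries
#' are left unchanged (closing is the identity on convex sets). Extensive
#' (`output >= input`), idempotent, per-slice (no resampling under
#' anisotropic slice spacing).
#'
#' @param mask a [binary_mask()].
#' @param ball_radius_mm radius (mm) of the largest boundary indentation
#'   that is guaranteed to be filled.
#' @return A repaired [binary_mask()].
#' @export
repair_contour <- function(mask, ball_radius_mm = 5) {
  if (ball_radius_mm <= 0)
    stop("ball_radius_mm must be > 0", call. = FALSE)
  a_px <- ball_radius_mm / mean(mask$spacing[2:3])
  if (a_px < 1) {
    warning("ball_radius_mm is smaller than one pixel; returning mask unchanged")
    return(mask)
  }
  r_px <- ceiling(1.4 * a_px^2 + 1)
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  pad <- r_px + 2L
  v <- mask$values
  d <- dim(v)
  out <- v
  for (k in seq_len(d[1])) {
    sl <- v[k, , ]
    if (!any(sl == 1L)) next
    # iterate to a fixpoint: closing one component can make it touch
    # another, and the merged component may close further (monotone, so
    # this terminates; one extra confirming pass in the common case)
    repeat {
      before <- sl
      lab <- label_components(sl, "plane4")
      for (l in seq_len(max(lab))) {
        idx <- which(lab == l, arr.ind = TRUE)
        i0 <- min(idx[, 1]); i1 <- max(idx[, 1])
        j0 <- min(idx[, 2]); j1 <- max(idx[, 2])
        canvas <- matrix(0L, i1 - i0 + 1L + 2L * pad, j1 - j0 + 1L + 2L * pad)
        canvas[cbind(idx[, 1] - i0 + 1L + pad, idx[, 2] - j0 + 1L + pad)] <- 1L
        cl <- EBImage::closing(canvas, brush)
        add <- which(cl > 0 & canvas == 0L, arr.ind = TRUE)
        if (nrow(add)) {
          ai <- add[, 1] - pad + i0 - 1L
          aj <- add[, 2] - pad + j0 - 1L
          ok <- ai >= 1L & ai <= d[2] & aj >= 1L & aj <= d[3]
          sl[cbind(ai[ok], aj[ok])] <- 1L
        }
      }
      if (identical(sl, before)) break
    }
    out[k, , ] <- sl
  }
  binary_mask(out, spacing = mask$spacing, origin = mask$origin)
}
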