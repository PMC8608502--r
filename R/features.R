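# Shape and intensity features of detected candidates.
#
# A candidate region is delineated by region growing from the centroid
# voxel: voxels with HU >= (centroid HU - growth_delta_hu), 26-connected,
# inside the lung mask, capped at a bounding box of half-width
# 2 * radius_mm per axis. Features are measured on that region.

# 26-connected dilation of a logical array by one voxel
.dilate26 <- function(m) {
  d <- dim(m)
  out <- m
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    zs <- pmin(pmax(seq_len(d[1]) + dz, 1L), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    xs <- pmin(pmax(seq_len(d[3]) + dx, 1L), d[3])
    out <- out | m[zs, ys, xs]
  }
  out
}

# 6-connected dilation (used for the surrounding shell)
.dilate6 <- function(m, iter = 1L) {
  d <- dim(m)
  for (it in seq_len(iter)) {
    out <- m
    for (ax_ in 1:3) for (s in c(-1L, 1L)) {
      ii <- pmin(pmax(seq_len(d[ax_]) + s, 1L), d[ax_])
      out <- out | switch(ax_, m[ii, , ], m[, ii, ], m[, , ii])
    }
    m <- out
  }
  m
}

# Vossepoel-Smeulders perimeter estimate from an 8-connected contour chain
.chain_perimeter <- function(contour) {
  if (nrow(contour) < 2) return(0)
  p <- rbind(contour, contour[1, ])
  st <- abs(diff(p))
  diag_ <- rowSums(st > 0) == 2
  0.980 * sum(!diag_) + 1.406 * sum(diag_)
}

#' Extract shape and intensity features for candidates
#'
#' For each candidate row, delineates a region by thresholded region
#' growing from the centroid (see Details) and measures: physical volume,
#' equivalent spherical diameter, circularity `4*pi*area / perimeter^2` on
#' the peak (largest-area) slice, elongation (major/minor principal axis
#' ratio from 3D second moments, in mm — tubular vessels score high,
#' spheres near 1), mean and max HU, contrast (region mean minus the mean
#' of a 2-voxel surrounding shell), and mean boundary gradient magnitude
#' (HU/mm). Contrast and gradient features are invariant to a constant HU
#' offset; mean/max HU shift with it.
#'
#' Candidates whose grown region has fewer than 3 voxels are flagged with
#' `feature_error = TRUE` and `NA` features rather than aborting the batch.
#'
#' @param volume a [ct_volume()].
#' @param mask lung [binary_mask()].
#' @param candidates candidate data frame from [detect_candidates()] (or a
#'   single row).
#' @param growth_delta_hu region growing tolerance below the centroid HU.
#' @return A data frame, one row per candidate: `volume_mm3`,
#'   `equivalent_diameter_mm`, `circularity`, `elongation`, `mean_hu`,
#'   `max_hu`, `contrast_hu`, `boundary_gradient_hu_per_mm`,
#'   `feature_error`.
#' @export
extract_features <- function(volume, mask, candidates, growth_delta_hu = 150) {
  out <- lapply(seq_len(nrow(candidates)), function(r)
    .features_one(volume, mask, candidates[r, ], growth_delta_hu))
  do.call(rbind, out)
}

.na_features <- function() {
  data.frame(volume_mm3 = NA_real_, equivalent_diameter_mm = NA_real_,
             circularity = NA_real_, elongation = NA_real_,
             mean_hu = NA_real_, max_hu = NA_real_, contrast_hu = NA_real_,
             boundary_gradient_hu_per_mm = NA_real_, feature_error = TRUE)
}

.features_one <- function(volume, mask, cand, growth_delta_hu) {
  d <- dim(volume$voxels)
  sp <- volume$spacing
  ci <- round(c(cand$k, cand$i, cand$j))
  ci <- pmin(pmax(ci, 1L), d)
  half <- ceiling(2 * cand$radius_mm / sp)
  lo <- pmax(ci - half, 1L)
  hi <- pmin(ci + half, d)
  sub <- volume$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msub <- mask$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  seed <- ci - lo + 1L
  seed_hu <- sub[seed[1], seed[2], seed[3]]
  eligible <- sub >= (seed_hu - growth_delta_hu) & msub == 1L
  region <- array(FALSE, dim = dim(sub))
  if (!eligible[seed[1], seed[2], seed[3]]) return(.na_features())
  region[seed[1], seed[2], seed[3]] <- TRUE
  repeat {
    grown <- .dilate26(region) & eligible
    if (sum(grown) == sum(region)) break
    region <- grown
  }
  nvox <- sum(region)
  if (nvox < 3) return(.na_features())

  vox_mm3 <- prod(sp)
  volume_mm3 <- nvox * vox_mm3
  eqd <- 2 * (3 * volume_mm3 / (4 * pi))^(1 / 3)

  # peak slice: largest in-plane area
  per_slice <- apply(region, 1, sum)
  pk <- which.max(per_slice)
  sl <- region[pk, , ] * 1L
  area <- sum(sl) * sp[2] * sp[3]
  oc <- EBImage::ocontour(sl)
  perim_px <- if (length(oc)) .chain_perimeter(oc[[1]]) else 0
  perim <- perim_px * mean(sp[2:3])
  circ <- if (perim > 0) min(4 * pi * area / perim^2, 1.1) else 1.1

  # elongation from 3D second moments (mm); add one voxel^2/12 so flat
  # regions do not give zero variance
  idx <- which(region, arr.ind = TRUE)
  pts <- sweep(idx, 2, sp, "*")
  cv <- stats::cov(pts)
  if (any(!is.finite(cv))) return(.na_features())
  cv <- cv + diag(sp^2) / 12
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  elong <- sqrt(max(ev[1], 0) / max(ev[3], 1e-9))

  hu <- sub[region]
  mean_hu <- mean(hu)
  max_hu <- max(hu)

  shell <- .dilate6(region, 2L) & !region
  shell_in_mask <- shell & msub == 1L
  if (sum(shell_in_mask) >= 10) shell <- shell_in_mask
  contrast <- if (any(shell)) mean_hu - mean(sub[shell]) else NA_real_

  # gradient magnitude on the region border (central differences, HU/mm)
  border <- region & !(.erode6(region))
  g <- .gradient_mag(sub, sp)
  bgrad <- mean(g[border])

  data.frame(volume_mm3 = volume_mm3, equivalent_diameter_mm = eqd,
             circularity = circ, elongation = elong, mean_hu = mean_hu,
             max_hu = max_hu, contrast_hu = contrast,
             boundary_gradient_hu_per_mm = bgrad, feature_error = FALSE)
}

.erode6 <- function(m) {
  d <- dim(m)
  out <- m
  for (ax_ in 1:3) for (s in c(-1L, 1L)) {
    ii <- pmin(pmax(seq_len(d[ax_]) + s, 1L), d[ax_])
    out <- out & switch(ax_, m[ii, , ], m[, ii, ], m[, , ii])
  }
  out
}

.gradient_mag <- function(v, sp) {
  d <- dim(v)
  g2 <- array(0, dim = d)
  for (ax_ in 1:3) {
    up <- pmin(seq_len(d[ax_]) + 1L, d[ax_])
    dn <- pmax(seq_len(d[ax_]) - 1L, 1L)
    hi <- switch(ax_, v[up, , ], v[, up, ], v[, , up])
    lo <- switch(ax_, v[dn, , ], v[, dn, ], v[, , dn])
    step <- pmin(up - dn, 2L)  # 1 at the edges, 2 inside
    stepa <- switch(ax_,
      array(rep(step, times = d[2] * d[3]), d),
      aperm(array(rep(step, times = d[1] * d[3]), c(d[2], d[1], d[3])), c(2, 1, 3)),
      aperm(array(rep(step, times = d[1] * d[2]), c(d[3], d[1], d[2])), c(2, 3, 1)))
    g2 <- g2 + ((hi - lo) / (stepa * sp[ax_]))^2
  }
  sqrt(g2)
}
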