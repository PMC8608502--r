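#' Variable-radius ring filter response
#'
#' Enhances compact bright shadows inside the lung by comparing, per slice
#' and per voxel, the mean HU over a disk of radius `r` with the mean HU
#' over the surrounding annulus (inner radius `r`, outer radius
#' `annulus_factor * r`), for every `r` in `radii_mm`; the response at a
#' voxel is the maximum disk-minus-annulus contrast over the searched
#' radii, floored at 0, and the maximizing radius is recorded (smallest
#' radius wins ties, so the output is deterministic). Both means are
#' restricted to in-mask pixels; if fewer than 25% of a voxel's annulus
#' pixels fall inside the mask the response is set to 0, which suppresses
#' pleural-edge artifacts. Radii are converted to pixels via the in-plane
#' spacing. Filtering is 2D per slice, so anisotropic slice spacing needs
#' no resampling.
#'
#' Both means are drawn from the mask eroded by one voxel (6-connectivity),
#' not the mask itself: voxels on the mask border carry partial-volume HU
#' blends of lung and chest-wall attenuation, and including them fires the
#' filter all along the pleural rim. Responses are still assigned at every
#' mask voxel; a voxel whose disk or annulus has less than 25% of its
#' pixels in the eroded mask gets response 0.
#'
#' The operator is purely contrast-based: adding a constant HU offset to
#' the whole volume leaves the response unchanged.
#'
#' @param volume a [ct_volume()].
#' @param mask lung [binary_mask()] on the same grid.
#' @param radii_mm ascending disk radii to search (mm); each must be at
#'   least one in-plane pixel.
#' @param annulus_factor outer/inner radius ratio of the annulus, > 1.
#' @return A `response_map`: list with `values` (3D array, HU contrast,
#'   zero outside the mask), `argmax_radius` (3D array, mm; NA where the
#'   response is 0), and `radii_mm`.
#' @export
ring_filter_response <- function(volume, mask,
                                 radii_mm = c(2, 3, 4, 6, 8, 10),
                                 annulus_factor = 1.6) {
  if (!length(radii_mm) || is.unsorted(radii_mm, strictly = TRUE))
    stop("radii_mm must be nonempty and strictly ascending", call. = FALSE)
  if (annulus_factor <= 1)
    stop("annulus_factor must be > 1", call. = FALSE)
  if (!identical(dim(volume$voxels), mask$parent_shape))
    stop("mask grid does not match volume grid", call. = FALSE)
  px_mm <- mean(volume$spacing[2:3])
  r_px <- radii_mm / px_mm
  if (any(r_px < 1))
    stop(sprintf("radius %.2f mm is smaller than one in-plane pixel (%.2f mm)",
                 radii_mm[which(r_px < 1)[1]], px_mm), call. = FALSE)

  kernels <- lapply(seq_along(radii_mm), function(s) {
    rr <- r_px[s]
    ro <- annulus_factor * rr
    half <- ceiling(ro)
    g <- seq(-half, half)
    dist <- sqrt(outer(g^2, g^2, "+"))
    list(disk = (dist <= rr) * 1, ring = (dist > rr & dist <= ro) * 1)
  })

  d <- dim(volume$voxels)
  resp <- array(0, dim = d)
  argr <- array(NA_real_, dim = d)
  mv <- mask$values
  src <- .erode_mask6(mv)  # mean sources: interior voxels only
  for (k in seq_len(d[1])) {
    full <- mv[k, , ]
    if (!any(full == 1L)) next
    msl <- src[k, , ]
    vsl <- volume$voxels[k, , ] * msl
    best <- matrix(0, d[2], d[3])
    bestr <- matrix(NA_real_, d[2], d[3])
    for (s in seq_along(kernels)) {
      kd <- kernels[[s]]$disk
      kr <- kernels[[s]]$ring
      num_d <- EBImage::filter2(vsl, kd, boundary = 0)
      den_d <- EBImage::filter2(msl + 0, kd, boundary = 0)
      num_r <- EBImage::filter2(vsl, kr, boundary = 0)
      den_r <- EBImage::filter2(msl + 0, kr, boundary = 0)
      ok <- den_d >= 0.25 * sum(kd) & den_r >= 0.25 * sum(kr)
      t_s <- matrix(0, d[2], d[3])
      t_s[ok] <- num_d[ok] / den_d[ok] - num_r[ok] / den_r[ok]
      upd <- t_s > best  # strict: earlier (smaller) radius wins ties
      best[upd] <- t_s[upd]
      bestr[upd] <- radii_mm[s]
    }
    best[best < 1e-6] <- 0  # clamp FFT float noise so flat regions are 0
    best[full == 0L] <- 0
    bestr[best == 0] <- NA_real_
    resp[k, , ] <- best
    argr[k, , ] <- bestr
  }
  structure(list(values = resp, argmax_radius = argr, radii_mm = radii_mm,
                 spacing = volume$spacing, origin = volume$origin),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf("<response_map> peak %.1f HU contrast, radii {%s} mm\n",
              max(x$values), paste(x$radii_mm, collapse = ", ")))
  invisible(x)
}

#' Detect suspected-nodule candidates from a response map
#'
#' Candidate seeds are local maxima of the response map: supra-threshold
#' voxels whose response equals the maximum over a surrounding box of
#' half-width `min_separation_mm` per axis. Seeds closer than
#' `min_separation_mm` (world distance) are merged keeping the higher
#' response (non-maximum suppression), and each surviving seed is refined
#' to the response-weighted centroid of the supra-threshold voxels within
#' its maximizing radius. The candidate's scale (`radius_mm`) is the
#' maximizing radius at the seed and its response is the seed's peak
#' value. Local maxima rather than connected-cluster centroids keep
#' nearby structures (a nodule beside a vessel tree) from collapsing into
#' one mislocalized candidate. The result is sorted by descending
#' response; lowering the threshold only ever adds seed locations.
#'
#' @param response a `response_map` from [ring_filter_response()].
#' @param mask lung [binary_mask()].
#' @param response_threshold minimum response (HU contrast).
#' @param min_separation_mm merge radius for nearby candidates (mm).
#' @return A candidate data frame with columns `k, i, j` (1-based voxel
#'   indices of the centroid), `z_mm, y_mm, x_mm`, `radius_mm`, `response`,
#'   `label`, `score` (the last two `NA` until classification).
#' @export
detect_candidates <- function(response, mask, response_threshold = 100,
                              min_separation_mm = 4) {
  sup <- response$values >= response_threshold & mask$values == 1L
  empty <- data.frame(k = numeric(0), i = numeric(0), j = numeric(0),
                      z_mm = numeric(0), y_mm = numeric(0), x_mm = numeric(0),
                      radius_mm = numeric(0), response = numeric(0),
                      label = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (!any(sup)) return(empty)
  rv <- response$values
  half <- pmax(floor(min_separation_mm / response$spacing), 1L)
  peaks <- sup & rv >= .box_max(rv, half)
  if (!any(peaks)) return(empty)
  idx <- which(peaks, arr.ind = TRUE)
  pr <- rv[peaks]
  ord <- order(-pr, idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]
  pr <- pr[ord]
  mm <- index_to_mm(response, idx)

  # non-maximum suppression: strongest first, drop seeds within range
  keep <- logical(length(pr))
  for (r in seq_along(pr)) {
    if (!any(keep)) { keep[r] <- TRUE; next }
    dd2 <- rowSums(sweep(mm[keep, , drop = FALSE], 2, mm[r, ], "-")^2)
    keep[r] <- all(dd2 >= min_separation_mm^2)
  }
  idx <- idx[keep, , drop = FALSE]
  pr <- pr[keep]

  sup_idx <- which(sup, arr.ind = TRUE)
  sup_mm <- index_to_mm(response, sup_idx)
  sup_w <- rv[sup]
  cand <- lapply(seq_along(pr), function(r) {
    pk <- idx[r, ]
    rad <- response$argmax_radius[pk[1], pk[2], pk[3]]
    ctr_mm <- index_to_mm(response, matrix(pk, ncol = 3))
    near <- rowSums(sweep(sup_mm, 2, as.numeric(ctr_mm), "-")^2) <= rad^2
    ww <- sup_w[near]
    ctr <- colSums(sup_idx[near, , drop = FALSE] * ww) / sum(ww)
    data.frame(k = ctr[1], i = ctr[2], j = ctr[3],
               radius_mm = rad, response = pr[r], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, cand)
  mmc <- index_to_mm(response, as.matrix(df[, c("k", "i", "j")]))
  df$z_mm <- mmc[, 1]; df$y_mm <- mmc[, 2]; df$x_mm <- mmc[, 3]
  df$label <- NA_character_
  df$score <- NA_real_
  rownames(df) <- NULL
  df[, c("k", "i", "j", "z_mm", "y_mm", "x_mm", "radius_mm", "response",
         "label", "score")]
}

# 6-connected erosion by one voxel; volumes one voxel thick in an axis
# are preserved in that axis (common for thin test stacks)
.erode_mask6 <- function(m) {
  d <- dim(m)
  out <- m
  for (ax_ in 1:3) {
    if (d[ax_] < 3L) next
    for (s in c(-1L, 1L)) {
      ii <- pmin(pmax(seq_len(d[ax_]) + s, 1L), d[ax_])
      out <- pmin(out, switch(ax_, m[ii, , ], m[, ii, ], m[, , ii]))
    }
  }
  out
}

# separable 3D box maximum with half-widths `half` (length 3, voxels)
.box_max <- function(v, half) {
  d <- dim(v)
  for (ax_ in 1:3) {
    h <- half[ax_]
    if (h < 1) next
    acc <- v
    for (s in seq_len(h)) {
      up <- pmin(seq_len(d[ax_]) + s, d[ax_])
      dn <- pmax(seq_len(d[ax_]) - s, 1L)
      acc <- pmax(acc,
                  switch(ax_, v[up, , ], v[, up, ], v[, , up]),
                  switch(ax_, v[dn, , ], v[, dn, ], v[, , dn]))
    }
    v <- acc
  }
  v
}
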