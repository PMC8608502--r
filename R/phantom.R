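#' Synthetic thoracic CT phantom specification
#'
#' Declarative description of a synthetic chest volume: an ellipsoidal
#' soft-tissue body containing two low-attenuation lung fields, bright
#' random-walk vessel tubes, spherical nodules with known ground truth, and
#' additive Gaussian noise. Defaults give a desk-scale but anisotropic grid
#' (64 slices of 128 x 128 at 2 x 1 x 1 mm) with tissue values at standard
#' CT attenuation: background air -1000 HU, body 40 HU, lung -850 HU,
#' vessels 50 HU.
#'
#' @param grid_shape integer length-3 `(slices, rows, cols)`.
#' @param spacing_mm numeric length-3 mm per axis `(slice, row, col)`.
#' @param body_semi_axes_mm,body_hu ellipsoid semi-axes `(z, y, x)` in mm and
#'   attenuation of the thorax body.
#' @param lung_semi_axes_mm semi-axes `(z, y, x)` of each lung field.
#' @param lung_offset_x_mm lateral offset of each lung center from the body
#'   center (mm).
#' @param lung_hu lung parenchyma attenuation.
#' @param vessel_count,vessel_radius_range_mm,vessel_hu random-walk vessel
#'   tubes per phantom, their radius range, and attenuation.
#' @param nodules list of [gt_nodule()] ground-truth nodules.
#' @param noise_sd_hu standard deviation of additive Gaussian noise (HU).
#' @param background_hu attenuation outside the body.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 128L, 128L),
                         spacing_mm = c(2, 1, 1),
                         body_semi_axes_mm = c(60, 55, 60),
                         body_hu = 40,
                         lung_semi_axes_mm = c(42, 36, 24),
                         lung_offset_x_mm = 30,
                         lung_hu = -850,
                         vessel_count = 8L,
                         vessel_radius_range_mm = c(1, 2.5),
                         vessel_hu = 50,
                         nodules = list(),
                         noise_sd_hu = 20,
                         background_hu = -1000) {
  center <- (grid_shape - 1) / 2 * spacing_mm
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
         body = list(center_mm = center, semi_axes_mm = as.numeric(body_semi_axes_mm),
                     hu = body_hu),
         lungs = list(
           list(center_mm = center + c(0, 0, -lung_offset_x_mm),
                semi_axes_mm = as.numeric(lung_semi_axes_mm), hu = lung_hu),
           list(center_mm = center + c(0, 0, lung_offset_x_mm),
                semi_axes_mm = as.numeric(lung_semi_axes_mm), hu = lung_hu)
         ),
         vessels = list(count = as.integer(vessel_count),
                        radius_range_mm = as.numeric(vessel_radius_range_mm),
                        hu = vessel_hu),
         nodules = nodules,
         noise_sd_hu = noise_sd_hu,
         background_hu = background_hu),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

#' Ground-truth nodule descriptor
#'
#' @param center_mm world mm `(z, y, x)` of the nodule center.
#' @param radius_mm nodule radius (mm), > 0.
#' @param hu nodule attenuation; must exceed the lung parenchyma HU.
#' @param placement one of `"isolated"`, `"juxtapleural"`, `"juxtavascular"`.
#' @return An object of class `gt_nodule`.
#' @export
gt_nodule <- function(center_mm, radius_mm, hu = 0,
                      placement = c("isolated", "juxtapleural", "juxtavascular")) {
  placement <- match.arg(placement)
  if (radius_mm <= 0) stop("nodule radius_mm must be > 0", call. = FALSE)
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 hu = hu, placement = placement),
            class = "gt_nodule")
}

# normalized ellipsoid radius of a point
.rho <- function(p, ell) sqrt(sum(((p - ell$center_mm) / ell$semi_axes_mm)^2))

#' Validate a phantom specification
#'
#' Checks the structural invariants: positive spacing and noise, lungs
#' strictly inside the body, nodule centers inside a lung (or on its
#' boundary for juxtapleural placement), nodules brighter than lung
#' parenchyma. Errors name the offending field.
#'
#' @param spec a [phantom_spec()].
#' @return `spec`, invisibly, if valid.
#' @export
validate_phantom_spec <- function(spec) {
  if (any(spec$spacing_mm <= 0))
    stop("phantom spec invalid: spacing_mm must be positive", call. = FALSE)
  if (spec$noise_sd_hu < 0)
    stop("phantom spec invalid: noise_sd_hu must be >= 0", call. = FALSE)
  # lungs inside body: sample each lung surface
  u <- .unit_dirs()
  for (li in seq_along(spec$lungs)) {
    lung <- spec$lungs[[li]]
    surf <- sweep(u %*% diag(lung$semi_axes_mm), 2, lung$center_mm, "+")
    rho_b <- sqrt(rowSums(
      sweep(sweep(surf, 2, spec$body$center_mm, "-"), 2,
            spec$body$semi_axes_mm, "/")^2))
    if (any(rho_b >= 1))
      stop(sprintf("phantom spec invalid: lungs[[%d]] not strictly inside body",
                   li), call. = FALSE)
  }
  for (ni in seq_along(spec$nodules)) {
    nd <- spec$nodules[[ni]]
    if (nd$hu <= spec$lungs[[1]]$hu)
      stop(sprintf("phantom spec invalid: nodules[[%d]]$hu must exceed lung hu",
                   ni), call. = FALSE)
    if (nd$radius_mm <= 0)
      stop(sprintf("phantom spec invalid: nodules[[%d]]$radius_mm must be > 0",
                   ni), call. = FALSE)
    rhos <- vapply(spec$lungs, function(l) .rho(nd$center_mm, l), numeric(1))
    if (nd$placement == "juxtapleural") {
      if (min(abs(rhos - 1)) > 0.2)
        stop(sprintf(
          "phantom spec invalid: nodules[[%d]]$center_mm not on a lung boundary",
          ni), call. = FALSE)
    } else if (min(rhos) > 1) {
      stop(sprintf("phantom spec invalid: nodules[[%d]]$center_mm not inside a lung",
                   ni), call. = FALSE)
    }
  }
  invisible(spec)
}

# fixed quasi-uniform direction set for surface checks
.unit_dirs <- function(n = 64L) {
  i <- seq_len(n)
  phi <- acos(1 - 2 * (i - 0.5) / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(phi), sin(phi) * sin(theta), sin(phi) * cos(theta))
}

# coordinate vectors (mm) along each axis for a spec grid
.axis_mm <- function(spec, origin = c(0, 0, 0)) {
  lapply(1:3, function(a)
    origin[a] + (seq_len(spec$grid_shape[a]) - 1) * spec$spacing_mm[a])
}

# squared normalized radius field of an ellipsoid over the full grid
.rho2_field <- function(ax, ell) {
  az <- ((ax[[1]] - ell$center_mm[1]) / ell$semi_axes_mm[1])^2
  ay <- ((ax[[2]] - ell$center_mm[2]) / ell$semi_axes_mm[2])^2
  axx <- ((ax[[3]] - ell$center_mm[3]) / ell$semi_axes_mm[3])^2
  outer(outer(az, ay, "+"), axx, "+")
}

# paint hu into v with coverage alpha (both arrays), in place semantics
.paint <- function(v, alpha, hu) {
  sel <- alpha > 0
  v[sel] <- v[sel] * (1 - alpha[sel]) + hu * alpha[sel]
  v
}

# smooth ellipsoid coverage from the rho^2 field; edge width in mm
.ellipsoid_alpha <- function(rho2, semi, edge = 1.5) {
  d <- (sqrt(rho2) - 1) * min(semi)  # approximate signed distance (mm)
  pmin(pmax(0.5 - d / edge, 0), 1)
}

# paint a sphere (center mm, radius mm, hu) into volume v over local bbox;
# optional restrict: logical array same dim as v (paint only where TRUE)
.paint_sphere <- function(v, ax, center, radius, hu, edge = 1.0,
                          restrict = NULL) {
  rng <- lapply(1:3, function(a) {
    which(abs(ax[[a]] - center[a]) <= radius + 2 * edge)
  })
  if (any(vapply(rng, length, integer(1)) == 0L)) return(v)
  dz <- (ax[[1]][rng[[1]]] - center[1])^2
  dy <- (ax[[2]][rng[[2]]] - center[2])^2
  dx <- (ax[[3]][rng[[3]]] - center[3])^2
  d <- sqrt(outer(outer(dz, dy, "+"), dx, "+"))
  alpha <- pmin(pmax(0.5 + (radius - d) / edge, 0), 1)
  if (!is.null(restrict))
    alpha <- alpha * restrict[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  sub <- v[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  sub <- .paint(sub, alpha, hu)
  v[rng[[1]], rng[[2]], rng[[3]]] <- sub
  v
}

# derive independent substream seeds (< 2^31) from one user seed
.substream_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 16807 + 12345) %% 2147483647
}

#' Generate a synthetic thoracic CT phantom
#'
#' Rasterizes the spec — background, body ellipsoid, two lung fields,
#' seeded random-walk vessel tubes inside the lungs, spherical nodules with
#' partial-volume shading at their boundary — then adds Gaussian noise.
#' The returned `lung_truth` is the noise-free lung rasterization;
#' juxtapleural nodules carve a matching notch in its boundary (a solid
#' nodule displaces the air-equivalent lung field there). Vessel and noise
#' draws use separate substreams of `seed`, so phantoms with and without
#' vessels share identical noise.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; same spec + seed is bit-reproducible.
#' @return A list with `volume` ([ct_volume()]), `lung_truth`
#'   ([binary_mask()]), and `nodules` (the spec's list of [gt_nodule()]).
#' @export
generate_phantom <- function(spec, seed = 1L) {
  validate_phantom_spec(spec)
  ax <- .axis_mm(spec)
  d <- spec$grid_shape
  v <- array(spec$background_hu, dim = d)

  body_rho2 <- .rho2_field(ax, spec$body)
  v <- .paint(v, .ellipsoid_alpha(body_rho2, spec$body$semi_axes_mm),
              spec$body$hu)

  lung_rho2 <- lapply(spec$lungs, function(l) .rho2_field(ax, l))
  for (li in seq_along(spec$lungs))
    v <- .paint(v, .ellipsoid_alpha(lung_rho2[[li]],
                                    spec$lungs[[li]]$semi_axes_mm),
                spec$lungs[[li]]$hu)
  lung_truth <- (lung_rho2[[1]] <= 1) | (lung_rho2[[2]] <= 1)

  # vessels: random-walk tubes confined to the lung interiors
  set.seed(.substream_seed(seed, 1L))
  interior <- (lung_rho2[[1]] <= 0.96) | (lung_rho2[[2]] <= 0.96)
  n_ves <- spec$vessels$count
  # vessels keep clear of isolated and juxtapleural nodules so placement
  # classes stay truthful (a nodule with a vessel through it would be
  # juxtavascular)
  avoid <- Filter(function(nd) nd$placement != "juxtavascular", spec$nodules)
  if (n_ves > 0) {
    for (vi in seq_len(n_ves)) {
      lung <- spec$lungs[[(vi - 1L) %% length(spec$lungs) + 1L]]
      v <- .paint_vessel(v, ax, lung, spec$vessels, restrict = interior,
                         avoid = avoid)
    }
  }
  # a dedicated vessel routed past each juxtavascular nodule
  for (nd in spec$nodules) {
    if (nd$placement == "juxtavascular") {
      li <- which.min(vapply(spec$lungs, function(l) .rho(nd$center_mm, l),
                             numeric(1)))
      v <- .paint_vessel(v, ax, spec$lungs[[li]], spec$vessels,
                         restrict = interior, through = nd, avoid = avoid)
    }
  }

  # nodules (painted after vessels so they overlie them)
  for (nd in spec$nodules)
    v <- .paint_sphere(v, ax, nd$center_mm, nd$radius_mm, nd$hu)

  # carve juxtapleural notches into the lung truth
  for (nd in spec$nodules) {
    if (nd$placement == "juxtapleural") {
      rng <- lapply(1:3, function(a)
        which(abs(ax[[a]] - nd$center_mm[a]) <= nd$radius_mm + 1))
      if (any(vapply(rng, length, integer(1)) == 0L)) next
      dz <- (ax[[1]][rng[[1]]] - nd$center_mm[1])^2
      dy <- (ax[[2]][rng[[2]]] - nd$center_mm[2])^2
      dx <- (ax[[3]][rng[[3]]] - nd$center_mm[3])^2
      dd <- sqrt(outer(outer(dz, dy, "+"), dx, "+"))
      sub <- lung_truth[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
      sub[dd <= nd$radius_mm] <- FALSE
      lung_truth[rng[[1]], rng[[2]], rng[[3]]] <- sub
    }
  }

  set.seed(.substream_seed(seed, 2L))
  if (spec$noise_sd_hu > 0)
    v <- v + stats::rnorm(length(v), 0, spec$noise_sd_hu)
  v <- round(v)

  list(
    volume = ct_volume(v, spacing = spec$spacing_mm,
                       source_id = sprintf("phantom(seed=%d)", as.integer(seed))),
    lung_truth = binary_mask(lung_truth, spacing = spec$spacing_mm),
    nodules = spec$nodules
  )
}

# one random-walk vessel tube inside `lung`; if `through` is a nodule, the
# walk starts tangent to its surface so the tube abuts the nodule; the walk
# stops before entering the clearance zone of any nodule in `avoid`
.paint_vessel <- function(v, ax, lung, vessels, restrict, through = NULL,
                          avoid = list()) {
  r <- stats::runif(1, vessels$radius_range_mm[1], vessels$radius_range_mm[2])
  if (is.null(through)) {
    # start near the hilum (medial third of the lung)
    p <- lung$center_mm + stats::rnorm(3) * lung$semi_axes_mm * 0.2
    dir <- stats::rnorm(3)
  } else {
    rad <- stats::rnorm(3)
    rad <- rad / sqrt(sum(rad^2))
    p <- through$center_mm + rad * (through$radius_mm + r * 0.8)
    # tangent direction: remove the radial component
    dir <- stats::rnorm(3)
    dir <- dir - sum(dir * rad) * rad
  }
  dir <- dir / sqrt(sum(dir^2))
  step <- 2
  for (s in seq_len(120L)) {
    if (.rho(p, lung) > 0.92) break
    too_close <- any(vapply(avoid, function(nd)
      sqrt(sum((p - nd$center_mm)^2)) < nd$radius_mm + r + 3, logical(1)))
    if (too_close) break
    v <- .paint_sphere(v, ax, p, r, vessels$hu, restrict = restrict)
    turn <- stats::rnorm(3, 0, 0.35)
    dir <- dir + turn
    dir <- dir / sqrt(sum(dir^2))
    p <- p + dir * step
  }
  v
}

#' Sample random ground-truth nodules for a phantom spec
#'
#' Draws nodule centers inside (or on the boundary of, for juxtapleural
#' placement) the spec's lung fields, keeping isolated nodules at least
#' `margin_mm + radius` away from the lung boundary and all nodules
#' mutually separated by `min_separation_mm` beyond their radii.
#'
#' @param spec a [phantom_spec()].
#' @param n number of nodules to draw.
#' @param placement nodule placement class (see [gt_nodule()]).
#' @param radius_range_mm radius range to draw from, mm.
#' @param hu nodule attenuation.
#' @param seed integer seed for the draw.
#' @param margin_mm boundary clearance for non-juxtapleural placement.
#' @param min_separation_mm surface-to-surface separation between nodules.
#' @return A list of [gt_nodule()].
#' @export
sample_nodules <- function(spec, n, placement = "isolated",
                           radius_range_mm = c(3, 8), hu = 0, seed = 1L,
                           margin_mm = 4, min_separation_mm = 6) {
  set.seed(.substream_seed(seed, 3L))
  out <- list()
  tries <- 0L
  while (length(out) < n && tries < 2000L) {
    tries <- tries + 1L
    lung <- spec$lungs[[(length(out) %% length(spec$lungs)) + 1L]]
    r <- stats::runif(1, radius_range_mm[1], radius_range_mm[2])
    if (placement == "juxtapleural") {
      u <- stats::rnorm(3)
      u[1] <- u[1] * 0.5  # avoid the lung poles where slices are tiny
      u <- u / sqrt(sum(u^2))
      surf <- lung$center_mm + u * lung$semi_axes_mm
      # sink the center 0.75 r below the pleural surface: the nodule
      # indents the lung field (~96% of its volume inside) rather than
      # sitting half outside in the chest wall
      inward <- lung$center_mm - surf
      inward <- inward / sqrt(sum(inward^2))
      center <- surf + inward * 0.75 * r
    } else {
      rho_max <- 1 - (r + margin_mm) / min(lung$semi_axes_mm)
      if (rho_max <= 0.05) next
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      rad <- rho_max * stats::runif(1)^(1 / 3)
      center <- lung$center_mm + u * rad * lung$semi_axes_mm
    }
    ok <- TRUE
    for (nd in out) {
      gap <- sqrt(sum((center - nd$center_mm)^2)) - r - nd$radius_mm
      if (gap < min_separation_mm) { ok <- FALSE; break }
    }
    if (ok)
      out[[length(out) + 1L]] <- gt_nodule(center, r, hu, placement)
  }
  if (length(out) < n)
    stop("sample_nodules: could not place the requested nodules", call. = FALSE)
  out
}

#' Write / read ground-truth nodules as CSV
#'
#' Columns: `z_mm, y_mm, x_mm, radius_mm, hu, placement`.
#'
#' @param nodules list of [gt_nodule()].
#' @param path output CSV path.
#' @export
write_truth <- function(nodules, path) {
  df <- data.frame(
    z_mm = vapply(nodules, function(n) n$center_mm[1], numeric(1)),
    y_mm = vapply(nodules, function(n) n$center_mm[2], numeric(1)),
    x_mm = vapply(nodules, function(n) n$center_mm[3], numeric(1)),
    radius_mm = vapply(nodules, function(n) n$radius_mm, numeric(1)),
    hu = vapply(nodules, function(n) n$hu, numeric(1)),
    placement = vapply(nodules, function(n) n$placement, character(1))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @param path CSV file written by [write_truth()].
#' @return `read_truth()`: a list of [gt_nodule()].
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    gt_nodule(c(df$z_mm[i], df$y_mm[i], df$x_mm[i]), df$radius_mm[i],
              df$hu[i], df$placement[i]))
}

#' Write / read a phantom spec as YAML
#'
#' @param spec a [phantom_spec()].
#' @param path YAML file path.
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  x$nodules <- lapply(spec$nodules, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$nodules <- lapply(x$nodules, function(nd)
    gt_nodule(unlist(nd$center_mm), nd$radius_mm, nd$hu, nd$placement))
  x$grid_shape <- as.integer(unlist(x$grid_shape))
  x$spacing_mm <- as.numeric(unlist(x$spacing_mm))
  for (f in c("center_mm", "semi_axes_mm"))
    x$body[[f]] <- as.numeric(unlist(x$body[[f]]))
  x$lungs <- lapply(x$lungs, function(l) {
    l$center_mm <- as.numeric(unlist(l$center_mm))
    l$semi_axes_mm <- as.numeric(unlist(l$semi_axes_mm))
    l
  })
  x$vessels$radius_range_mm <- as.numeric(unlist(x$vessels$radius_range_mm))
  spec <- structure(x, class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}
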