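test_that("isodata threshold finds the exact midpoint of a two-valued volume", {
  v <- ct_volume(array(rep(c(-1000, 0), 500), c(10, 10, 10)), c(1, 1, 1))
  res <- optimal_threshold(v)
  expect_equal(res$threshold, -500)
  expect_equal(unname(res$class_means), c(-1000, 0))
})

test_that("isodata threshold matches the exhaustive fixed-point scan oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    v <- c(rnorm(5e4, -800, 50), rnorm(5e4, -100, 50))
    res <- optimal_threshold(array(v, c(100, 100, 10)))
    oracle <- oracle_isodata_scan(v)
    expect_lt(abs(res$threshold - oracle), 1 + 1e-9,
              label = sprintf("seed %d: |%.2f - %d|", seed, res$threshold,
                              oracle))
    # fixed point and class-mean bracketing
    expect_lt(abs(res$threshold - mean(res$class_means)), 0.5 + 1e-9)
    expect_gt(res$threshold, res$class_means[1])
    expect_lt(res$threshold, res$class_means[2])
  }
})

test_that("degenerate threshold inputs raise errors", {
  v <- ct_volume(array(-1000, c(3, 3, 3)), c(1, 1, 1))
  expect_error(optimal_threshold(v), "degenerate")
  set.seed(2)
  mix <- array(c(rnorm(500, -800, 50), rnorm(500, -100, 50)), c(10, 10, 10))
  expect_error(optimal_threshold(mix, tolerance = 1e-12, max_iter = 1L),
               "converge")
})

test_that("lung extraction keeps the two lung ellipses and drops ambient air", {
  # one synthetic slice stack: soft-tissue disk containing two air ellipses
  d <- c(3, 64, 64)
  v <- array(-1000, d)
  truth <- array(0L, d)
  for (i in 1:64) for (j in 1:64) {
    if ((i - 32)^2 + (j - 32)^2 <= 28^2) v[, i, j] <- 40
    for (s in c(-1, 1)) {
      if ((i - 32)^2 / 100 + (j - 32 - s * 14)^2 / 49 <= 1) {
        v[, i, j] <- -850
        truth[, i, j] <- 1L
      }
    }
  }
  vol <- ct_volume(v, c(2, 1, 1))
  m <- extract_lung_mask(vol, optimal_threshold(vol), min_volume_ml = 0.1)
  expect_identical(m$values, truth)
})

test_that("lung extraction reaches Dice >= 0.95 against phantom truth", {
  ph <- default_phantom(seed = 1)
  m <- extract_lung_mask(ph$volume, optimal_threshold(ph$volume),
                         min_volume_ml = 50)
  expect_gte(dice(m, ph$lung_truth), 0.95)
  # no mask voxel face-connected to the volume border air
  expect_equal(sum(m$values[1, , ]) + sum(m$values[, 1, ]) +
                 sum(m$values[, , 1]), 0)
})

test_that("an all-air volume is a segmentation failure", {
  v <- ct_volume(array(rep(c(-1000, -990), 500), c(10, 10, 10)), c(1, 1, 1))
  expect_error(extract_lung_mask(v, -500, min_volume_ml = 1),
               "segmentation failure")
})

test_that("cavity filling fills interior holes and counts voxels exactly", {
  m <- array(0L, c(1, 20, 20))
  m[1, 5:15, 5:15] <- 1L
  m[1, 9:11, 9:11] <- 0L  # 3x3 interior hole
  msk <- binary_mask(m, c(1, 1, 1))
  filled <- fill_cavities(msk)
  expect_equal(sum(filled$values) - sum(msk$values), 9)
  expect_true(all(filled$values >= msk$values))
  # no holes -> identical output; idempotent on its own output
  expect_identical(fill_cavities(filled)$values, filled$values)
})

test_that("cavity filling restores a dense nodule excluded by thresholding", {
  spec <- phantom_spec(
    nodules = list(gt_nodule(c(64, 63.5, 93.5), radius_mm = 6, hu = 40)),
    vessel_count = 0L, noise_sd_hu = 10)
  ph <- generate_phantom(spec, seed = 4)
  raw_mask <- extract_lung_mask(ph$volume, optimal_threshold(ph$volume),
                                min_volume_ml = 50)
  filled <- fill_cavities(raw_mask)
  # nodule interior truth voxels
  ax <- lapply(1:3, function(a) (seq_len(dim(ph$volume$voxels)[a]) - 1) *
                 ph$volume$spacing[a])
  nd <- spec$nodules[[1]]
  dist <- sqrt(outer(outer((ax[[1]] - nd$center_mm[1])^2,
                           (ax[[2]] - nd$center_mm[2])^2, "+"),
                     (ax[[3]] - nd$center_mm[3])^2, "+"))
  inside <- dist <= nd$radius_mm - 1
  expect_lt(mean(raw_mask$values[inside]), 0.5)   # excluded by threshold
  expect_gte(mean(filled$values[inside]), 0.99)   # recovered by filling
})

test_that("contour repair fills a notch but leaves convex masks unchanged", {
  # disk of radius 20 mm with a hemispherical boundary notch of radius
  # 3 mm, sampled at 0.5 mm pixels
  d <- c(1, 128, 128)
  notched <- array(0L, d)
  notch <- array(FALSE, d)
  for (i in 1:128) for (j in 1:128) {
    x <- (i - 64) * 0.5; y <- (j - 64) * 0.5
    in_disk <- x^2 + y^2 <= 20^2
    in_notch <- x^2 + (y + 20)^2 <= 3^2  # centered on the boundary
    notched[1, i, j] <- as.integer(in_disk && !in_notch)
    notch[1, i, j] <- in_disk && in_notch
  }
  rep_ <- repair_contour(binary_mask(notched, c(1, 0.5, 0.5)),
                         ball_radius_mm = 5)
  expect_gte(mean(rep_$values[notch]), 0.95)
  expect_true(all(rep_$values >= notched))

  # convex ellipse: closing is the identity
  ell <- array(0L, c(1, 64, 64))
  for (i in 1:64) for (j in 1:64)
    ell[1, i, j] <- as.integer((i - 32)^2 / 400 + (j - 32)^2 / 100 <= 1)
  conv <- binary_mask(ell, c(1, 1, 1))
  expect_identical(repair_contour(conv, 5)$values, conv$values)
})

test_that("repair warns and is the identity for sub-pixel radii", {
  m <- binary_mask(array(1L, c(1, 4, 4)), c(1, 2, 2))
  expect_warning(out <- repair_contour(m, 0.5), "pixel")
  expect_identical(out$values, m$values)
  expect_error(repair_contour(m, -1), "> 0")
})

test_that("juxtapleural nodules are recovered into the lung mask by repair", {
  nodules <- sample_nodules(phantom_spec(), 2, placement = "juxtapleural",
                            radius_range_mm = c(3, 4.5), seed = 8)
  spec <- phantom_spec(nodules = nodules, vessel_count = 0L)
  ph <- generate_phantom(spec, seed = 5)
  m0 <- fill_cavities(extract_lung_mask(ph$volume,
                                        optimal_threshold(ph$volume),
                                        min_volume_ml = 50))
  m1 <- repair_contour(m0, ball_radius_mm = 5)
  # paired control: the same phantom without nodules (identical noise by
  # the substream design) tells us which nodule voxels a
  # threshold-segmented lung would cover at all -- repair cannot recover
  # boundary voxels that thresholding never includes
  ref <- generate_phantom(phantom_spec(vessel_count = 0L), seed = 5)
  mref <- repair_contour(fill_cavities(extract_lung_mask(
    ref$volume, optimal_threshold(ref$volume), min_volume_ml = 50)), 5)
  ax <- lapply(1:3, function(a) (seq_len(dim(ph$volume$voxels)[a]) - 1) *
                 ph$volume$spacing[a])
  for (nd in spec$nodules) {
    dist <- sqrt(outer(outer((ax[[1]] - nd$center_mm[1])^2,
                             (ax[[2]] - nd$center_mm[2])^2, "+"),
                       (ax[[3]] - nd$center_mm[3])^2, "+"))
    nod <- dist <= nd$radius_mm & mref$values == 1L
    expect_lt(mean(m0$values[nod]), 0.5)   # notched out before repair
    expect_gte(mean(m1$values[nod]), 0.9)  # recovered by repair
  }
})

test_that("filling and repair are extensive and idempotent on random masks", {
  set.seed(99)
  for (rep_i in 1:8) {
    m <- array(0L, c(2, 40, 40))
    for (b in 1:5) {
      ci <- sample(8:32, 1); cj <- sample(8:32, 1); r <- sample(3:7, 1)
      for (i in 1:40) for (j in 1:40)
        if ((i - ci)^2 + (j - cj)^2 <= r^2) m[, i, j] <- 1L
    }
    msk <- binary_mask(m, c(2, 1, 1))
    f1 <- fill_cavities(msk)
    expect_true(all(f1$values >= msk$values))
    expect_identical(fill_cavities(f1)$values, f1$values)
    r1 <- repair_contour(msk, 4)
    expect_true(all(r1$values >= msk$values))
    expect_identical(repair_contour(r1, 4)$values, r1$values)
  }
})
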