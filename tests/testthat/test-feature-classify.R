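# build an isotropic volume containing one ellipsoidal "nodule"
ellipsoid_volume <- function(semi_mm = c(5, 5, 5), hu = -450, bg = -850,
                             spacing = c(1, 1, 1), shape = c(40, 40, 40)) {
  ctr <- (shape + 1) / 2 * spacing
  ax <- lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a] +
                 spacing[a] / 2)
  rho2 <- outer(outer(((ax[[1]] - ctr[1]) / semi_mm[1])^2,
                      ((ax[[2]] - ctr[2]) / semi_mm[2])^2, "+"),
                ((ax[[3]] - ctr[3]) / semi_mm[3])^2, "+")
  v <- array(bg, shape)
  v[rho2 <= 1] <- hu
  list(volume = ct_volume(v, spacing),
       mask = binary_mask(array(1L, shape), spacing),
       inside = rho2 <= 1,
       cand = data.frame(k = (shape[1] + 1) / 2, i = (shape[2] + 1) / 2,
                         j = (shape[3] + 1) / 2,
                         radius_mm = max(semi_mm), response = 400))
}

test_that("a solid sphere yields sphere-like features", {
  fx <- ellipsoid_volume(semi_mm = c(5, 5, 5))
  f <- extract_features(fx$volume, fx$mask, fx$cand)
  expect_false(f$feature_error)
  expect_gte(f$circularity, 0.9)
  expect_lte(f$elongation, 1.1)
  expect_equal(f$equivalent_diameter_mm, 10, tolerance = 0.1)
  expect_equal(f$mean_hu, -450)
  expect_equal(f$contrast_hu, 400)
})

test_that("elongation matches the brute-force moment oracle on a 2:1 ellipsoid", {
  fx <- ellipsoid_volume(semi_mm = c(4, 8, 4))
  f <- extract_features(fx$volume, fx$mask, fx$cand)
  pts <- which(fx$inside, arr.ind = TRUE) * 1.0
  oracle <- oracle_axis_ratio(pts)
  expect_equal(f$elongation, 2.0, tolerance = 0.2)
  expect_equal(f$elongation, oracle, tolerance = 0.1)
})

test_that("contrast features are offset-invariant, intensity features shift", {
  fx <- ellipsoid_volume()
  f0 <- extract_features(fx$volume, fx$mask, fx$cand)
  shifted <- ct_volume(fx$volume$voxels + 200, fx$volume$spacing)
  f1 <- extract_features(shifted, fx$mask, fx$cand)
  expect_equal(f1$contrast_hu, f0$contrast_hu)
  expect_equal(f1$boundary_gradient_hu_per_mm, f0$boundary_gradient_hu_per_mm)
  expect_equal(f1$circularity, f0$circularity)
  expect_equal(f1$mean_hu, f0$mean_hu + 200)
  expect_equal(f1$max_hu, f0$max_hu + 200)
})

test_that("degenerate regions are flagged, not fatal", {
  # single bright voxel: grown region stays < 3 voxels
  v <- array(-850, c(9, 9, 9)); v[5, 5, 5] <- 100
  vol <- ct_volume(v, c(1, 1, 1))
  msk <- binary_mask(array(1L, c(9, 9, 9)), c(1, 1, 1))
  f <- extract_features(vol, msk, data.frame(k = 5, i = 5, j = 5,
                                             radius_mm = 1, response = 900))
  expect_true(f$feature_error)
  expect_true(is.na(f$volume_mm3))
  # flagged candidates get the negative class
  cls <- classify_candidates(f, rule_model())
  expect_equal(cls$label, "non_nodule")
  expect_equal(cls$score, 0)
})

test_that("the linear discriminant separates well-separated clouds perfectly", {
  set.seed(31)
  n <- 100
  pos <- matrix(rnorm(n * 4, 3), n, 4)
  neg <- matrix(rnorm(n * 4, 0), n, 4)
  x <- rbind(pos, neg)
  colnames(x) <- paste0("f", 1:4)
  y <- rep(c("nodule", "non_nodule"), each = n)
  model <- fit_classifier(x, y, class_names = c("non_nodule", "nodule"))
  pred <- classify_candidates(as.data.frame(x), model)
  expect_equal(mean(pred$label == y), 1)
  expect_true(all(pred$score[1:n] > 0.5))
})

test_that("held-out accuracy approaches the analytic Bayes rate", {
  set.seed(77)
  d <- 3; delta <- 1; n <- 1000
  make <- function(n, mu) matrix(rnorm(n * d, mu), n, d,
                                 dimnames = list(NULL, paste0("f", 1:d)))
  xtr <- rbind(make(n, 0), make(n, delta))
  ytr <- rep(c("a", "b"), each = n)
  xte <- rbind(make(n, 0), make(n, delta))
  yte <- rep(c("a", "b"), each = n)
  model <- fit_classifier(xtr, ytr)
  acc <- 100 * mean(classify_candidates(as.data.frame(xte), model)$label == yte)
  bayes <- oracle_bayes_accuracy(delta, d)  # closed form for equal Gaussians
  expect_lt(abs(acc - bayes), 5)
})

test_that("the discriminant agrees with an independent LDA implementation", {
  set.seed(13)
  n <- 80
  x <- rbind(matrix(rnorm(n * 3, 0), n, 3), matrix(rnorm(n * 3, 1.5), n, 3))
  colnames(x) <- c("u", "v", "w")
  y <- rep(c("a", "b"), each = n)
  model <- fit_classifier(x, y)
  mine <- classify_candidates(as.data.frame(x), model)$label
  ref <- as.character(predict(MASS::lda(x, grouping = y))$class)
  expect_gte(mean(mine == ref), 0.98)
})

test_that("degenerate training inputs error or regularize", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_classifier(x, rep("one", 20)), "2 classes")
  expect_error(fit_classifier(x[1:3, ], c("a", "a", "b")), "2 examples")
  # collinear features: warns and still returns a usable model
  xc <- cbind(f1 = rnorm(40), f2 = 0)
  xc[21:40, 1] <- xc[21:40, 1] + 5
  xc[, 2] <- xc[, 1] * 2
  expect_warning(m <- fit_classifier(xc, rep(c("a", "b"), each = 20)),
                 "singular")
  expect_equal(length(m$weights), 2)
})

test_that("a zero-weight linear model scores 0.5 for any features", {
  model <- structure(
    list(kind = "linear", class_names = c("neg", "pos"),
         weights = c(0, 0), bias = 0, center = c(0, 0), scale = c(1, 1),
         feature_names = c("f1", "f2")),
    class = "cad_model")
  out <- classify_candidates(data.frame(f1 = c(-10, 0, 99),
                                        f2 = c(5, 0, -1)), model)
  expect_equal(out$score, rep(0.5, 3))
})

test_that("the decision is invariant to consistent affine feature rescaling", {
  set.seed(5)
  n <- 60
  x <- rbind(matrix(rnorm(n * 2, 0), n, 2), matrix(rnorm(n * 2, 2), n, 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("a", "b"), each = n)
  m1 <- fit_classifier(x, y)
  x2 <- x; x2[, 1] <- x2[, 1] * 1000 - 37  # rescale one feature everywhere
  m2 <- fit_classifier(x2, y)
  s1 <- classify_candidates(as.data.frame(x), m1)$score
  s2 <- classify_candidates(as.data.frame(x2), m2)$score
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("rule-based screening rejects by size and scores partial passes", {
  f <- data.frame(volume_mm3 = 20, equivalent_diameter_mm = 2,
                  circularity = 0.95, elongation = 1.1, mean_hu = 0,
                  max_hu = 30, contrast_hu = 700,
                  boundary_gradient_hu_per_mm = 300, feature_error = FALSE)
  out <- classify_candidates(f, rule_model())
  expect_equal(out$label, "non_nodule")  # fails the min-diameter rule
  expect_equal(out$score, 0.75)          # 3 of 4 rules passed
  f$equivalent_diameter_mm <- 8
  expect_equal(classify_candidates(f, rule_model())$label, "nodule")
})

test_that("rule screening keeps compact phantom truth nodules", {
  ph <- nodule_phantom(seed = 3)
  mask <- segmented_mask(ph)
  cands <- detect_candidates(ring_filter_response(ph$volume, mask), mask)
  feats <- extract_features(ph$volume, mask, cands)
  cls <- classify_candidates(feats, rule_model())
  for (nd in ph$nodules) {
    dd <- sqrt((cands$z_mm - nd$center_mm[1])^2 +
                 (cands$y_mm - nd$center_mm[2])^2 +
                 (cands$x_mm - nd$center_mm[3])^2)
    hit <- which(dd <= max(5, nd$radius_mm))
    expect_true(any(cls$label[hit] == "nodule"),
                label = sprintf("nodule r=%.1f kept", nd$radius_mm))
  }
})

test_that("models persist as JSON and round-trip", {
  td <- withr::local_tempdir()
  rm_ <- rule_model(min_diameter_mm = 4.5)
  p <- file.path(td, "rule.json")
  save_model(rm_, p)
  back <- load_model(p)
  expect_equal(back$thresholds$min_diameter_mm, 4.5)
  expect_equal(back$kind, "rule_based")

  set.seed(1)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 3), 20, 2))
  colnames(x) <- c("f1", "f2")
  lm_ <- fit_classifier(x, rep(c("a", "b"), each = 20))
  p2 <- file.path(td, "lin.json")
  save_model(lm_, p2)
  back2 <- load_model(p2)
  newx <- data.frame(f1 = rnorm(10), f2 = rnorm(10))
  expect_equal(classify_candidates(newx, back2), classify_candidates(newx, lm_))
})
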