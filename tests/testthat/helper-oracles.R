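# Independent oracles used by the test suite. These deliberately use
# brute force / closed forms, not the package's own code paths.

# exhaustive fixed-point scan for the isodata threshold: the integer HU
# minimizing |T - (mean below + mean above)/2|
oracle_isodata_scan <- function(v) {
  ts <- seq(ceiling(min(v)) + 1, floor(max(v)))
  err <- vapply(ts, function(t) {
    lo <- v < t
    if (!any(lo) || all(lo)) return(Inf)
    abs(t - (mean(v[lo]) + mean(v[!lo])) / 2)
  }, numeric(1))
  ts[which.min(err)]
}

# direct disk/annulus mean contrast at one pixel of one slice
oracle_ring_response <- function(slice, ci, cj, r_px, annulus_factor) {
  d <- dim(slice)
  best <- -Inf
  for (r in r_px) {
    ro <- annulus_factor * r
    disk <- c(); ring <- c()
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      dd <- sqrt((i - ci)^2 + (j - cj)^2)
      if (dd <= r) disk <- c(disk, slice[i, j])
      else if (dd <= ro) ring <- c(ring, slice[i, j])
    }
    best <- max(best, mean(disk) - mean(ring))
  }
  max(best, 0)
}

# Bayes error rate for two unit-variance d-dimensional Gaussians with
# equal priors and mean separation delta per feature: misclassification
# probability is pnorm(-||mu1 - mu0|| / 2)
oracle_bayes_accuracy <- function(delta_per_feature, d) {
  100 * stats::pnorm(sqrt(d) * delta_per_feature / 2)
}

# axis ratio of an ellipsoid region by brute-force second moments over
# its voxel index set (points in mm)
oracle_axis_ratio <- function(pts_mm) {
  ev <- sort(eigen(stats::cov(pts_mm), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  sqrt(ev[1] / ev[length(ev)])
}

# greedy score of the printed aggregate: construct geometry reproducing
# given counts (used by the evaluation worked example)
make_aggregate_sets <- function(n_sets, n_true, n_matched, n_fp) {
  truth_per_set <- list()
  cand_per_set <- list()
  ti <- 0; mi <- 0; fi <- 0
  for (s in seq_len(n_sets)) {
    nt <- n_true %/% n_sets + (s <= n_true %% n_sets)
    truth <- lapply(seq_len(nt), function(t)
      lungcad::gt_nodule(c(10 * s, 30 * t, 0), radius_mm = 4, hu = 0))
    nm <- min(nt, max(0, n_matched - mi)); mi <- mi + nm
    nf <- n_fp %/% n_sets + (s <= n_fp %% n_sets)
    mk <- function(n, x_mm, response) {
      data.frame(k = rep(1, n), i = rep(1, n), j = rep(1, n),
                 z_mm = rep(10 * s, n), y_mm = 30 * seq_len(n),
                 x_mm = rep(x_mm, n), radius_mm = rep(4, n),
                 response = rep(response, n), label = rep("nodule", n),
                 score = rep(1, n), stringsAsFactors = FALSE)
    }
    cands <- rbind(mk(nm, 0, 500), mk(nf, 500, 200))  # FPs 500 mm away
    truth_per_set[[s]] <- truth
    cand_per_set[[s]] <- cands
  }
  list(truth = truth_per_set, candidates = cand_per_set)
}
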