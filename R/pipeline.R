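#' Default pipeline configuration
#'
#' Nested list of every tunable stage parameter, overridable via a YAML
#' file ([read_config()]) or by name. `default_config()` carries
#' clinical-scale defaults (400 ml minimum lung volume);
#' [phantom_config()] is the same configuration with the lung-volume floor
#' scaled down to 50 ml for the desk-scale synthetic phantoms, whose lungs
#' hold roughly 150 ml each.
#'
#' @param ... named overrides using dotted keys, e.g.
#'   `default_config("lung.min_volume_ml" = 50)`.
#' @return A nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    threshold = list(tolerance_hu = 0.5, max_iter = 100L),
    lung = list(min_volume_ml = 400, keep_components = 2L,
                remove_airway = FALSE),
    repair = list(ball_radius_mm = 5),
    detect = list(radii_mm = c(2, 3, 4, 6, 8, 10), annulus_factor = 1.6,
                  response_threshold = 100, min_separation_mm = 4),
    features = list(growth_delta_hu = 150),
    classify = list(mode = "rule_based", min_diameter_mm = 3,
                    min_circularity = 0.5, max_elongation = 2.5,
                    min_contrast_hu = 150, model_path = NULL),
    evaluate = list(hit_distance_mm = 5)
  )
  .config_override(cfg, list(...))
}

#' @rdname default_config
#' @export
phantom_config <- function(...) {
  default_config("lung.min_volume_ml" = 50, ...)
}

.config_override <- function(cfg, overrides) {
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      cfg[[parts[1]]][[parts[2]]] <- overrides[[key]]
    } else {
      cfg[[key]] <- overrides[[key]]
    }
  }
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' Unknown keys are rejected so typos in config files fail loudly.
#' Keys omitted from the file keep their defaults.
#'
#' @param path YAML file with namespaced sections (threshold, lung,
#'   repair, detect, features, classify, evaluate).
#' @param base configuration to override, default [default_config()].
#' @return A nested configuration list.
#' @export
read_config <- function(path, base = default_config()) {
  y <- yaml::read_yaml(path)
  for (sec in names(y)) {
    if (!sec %in% names(base))
      stop("config error: unknown section '", sec, "'", call. = FALSE)
    for (key in names(y[[sec]])) {
      if (!key %in% names(base[[sec]]))
        stop("config error: unknown key '", sec, ".", key, "'", call. = FALSE)
      val <- y[[sec]][[key]]
      if (is.null(val)) next  # explicit nulls keep the default
      if (is.list(val)) val <- unlist(val)
      base[[sec]][[key]] <- val
    }
  }
  base
}

#' @rdname read_config
#' @param config configuration list to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full CAD pipeline on one volume
#'
#' Chains the implemented stages in order: read, optimal threshold, lung
#' extraction, cavity filling, contour repair, ring-filter response,
#' candidate detection, feature extraction, classification. Writes the
#' repaired lung mask, the candidate CSVs (all candidates, and those the
#' classifier accepted), optionally the response map, and a JSON report
#' with per-stage counts, timings and the configuration snapshot. With a
#' fixed configuration and input, repeated runs produce byte-identical
#' candidate CSVs (no stage is stochastic).
#'
#' @param input path to a DICOM directory or a single-file volume
#'   (NIfTI / MetaImage), or a [ct_volume()] directly.
#' @param output_dir directory for outputs (created if missing).
#' @param config configuration list (see [default_config()]).
#' @param save_response also write the ring-filter response map.
#' @return A `detection_report`: list with `stages` (per-stage counts and
#'   timings), `candidates` (all) and `accepted` (screened) frames,
#'   `config`, and output `paths`.
#' @export
run_pipeline <- function(input, output_dir, config = default_config(),
                         save_response = FALSE) {
  if (is.character(input) && !file.exists(input) && !dir.exists(input))
    stop("input error: no such file or directory: ", input, call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    stages[[stage]] <<- list(seconds = proc.time()[["elapsed"]] - t0)
    res
  }

  volume <- clock("read", {
    if (inherits(input, "ct_volume")) input
    else if (dir.exists(input)) read_dicom_series(input)
    else read_volume(input)
  })
  stages$read$voxels <- length(volume$voxels)

  thr <- clock("threshold", optimal_threshold(
    volume, tolerance = config$threshold$tolerance_hu,
    max_iter = config$threshold$max_iter))
  stages$threshold$threshold_hu <- thr$threshold

  mask <- clock("lung_mask", extract_lung_mask(
    volume, thr, min_volume_ml = config$lung$min_volume_ml,
    keep_components = config$lung$keep_components,
    remove_airway = config$lung$remove_airway))
  mask <- clock("fill_cavities", fill_cavities(mask))
  mask <- clock("repair_contour", repair_contour(
    mask, ball_radius_mm = config$repair$ball_radius_mm))
  stages$repair_contour$lung_ml <- sum(mask$values) * prod(mask$spacing) / 1000

  resp <- clock("ring_filter", ring_filter_response(
    volume, mask, radii_mm = config$detect$radii_mm,
    annulus_factor = config$detect$annulus_factor))
  cands <- clock("detect", detect_candidates(
    resp, mask, response_threshold = config$detect$response_threshold,
    min_separation_mm = config$detect$min_separation_mm))
  stages$detect$candidates <- nrow(cands)

  feats <- clock("features", if (nrow(cands))
    extract_features(volume, mask, cands,
                     growth_delta_hu = config$features$growth_delta_hu)
    else NULL)

  model <- if (config$classify$mode == "linear" &&
               !is.null(config$classify$model_path)) {
    load_model(config$classify$model_path)
  } else {
    rule_model(min_diameter_mm = config$classify$min_diameter_mm,
               min_circularity = config$classify$min_circularity,
               max_elongation = config$classify$max_elongation,
               min_contrast_hu = config$classify$min_contrast_hu)
  }
  accepted <- clock("classify", {
    if (nrow(cands)) {
      cls <- classify_candidates(feats, model)
      cands$label <- cls$label
      cands$score <- cls$score
      cands[cands$label == model$class_names[2], , drop = FALSE]
    } else cands
  })
  stages$classify$accepted <- nrow(accepted)

  paths <- list(
    lung_mask = file.path(output_dir, "lung_mask.nii.gz"),
    candidates = file.path(output_dir, "candidates.csv"),
    accepted = file.path(output_dir, "candidates_accepted.csv"),
    report = file.path(output_dir, "report.json")
  )
  write_volume(mask, paths$lung_mask)
  write_candidates(cands, paths$candidates)
  write_candidates(accepted, paths$accepted)
  if (save_response) {
    paths$response <- file.path(output_dir, "response.nii.gz")
    rv <- ct_volume(round(resp$values), volume$spacing, volume$origin,
                    source_id = "response_map")
    write_volume(rv, paths$response)
  }
  report <- structure(
    list(source = volume$source_id, stages = stages,
         candidates = cands, accepted = accepted,
         config = config, paths = paths),
    class = "detection_report"
  )
  jsonlite::write_json(
    list(source = volume$source_id, stages = stages, config = config,
         n_candidates = nrow(cands), n_accepted = nrow(accepted)),
    paths$report, auto_unbox = TRUE, digits = NA, pretty = TRUE,
    force = TRUE, null = "null")
  report
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> %s\n", x$source))
  for (s in names(x$stages)) {
    extra <- setdiff(names(x$stages[[s]]), "seconds")
    info <- if (length(extra))
      paste(vapply(extra, function(e)
        sprintf("%s=%s", e, format(x$stages[[s]][[e]], digits = 4)),
        character(1)), collapse = ", ")
      else ""
    cat(sprintf("  %-15s %6.2fs  %s\n", s, x$stages[[s]]$seconds, info))
  }
  cat(sprintf("  candidates: %d detected, %d accepted\n",
              nrow(x$candidates), nrow(x$accepted)))
  invisible(x)
}

#' Build an evaluation result from aggregate counts
#'
#' The arithmetic of CAD detection scoring: sensitivity (detection rate)
#' is `100 * n_detected / n_true`, the per-set false-positive average is
#' `n_fp / n_sets` (reported exact and rounded to the nearest integer).
#'
#' @param n_true annotated nodules.
#' @param n_detected nodules matched by at least one candidate.
#' @param n_fp candidates matching no nodule.
#' @param n_sets number of image sets (scans).
#' @return An `eval_result` list: `n_true`, `n_detected`, `n_missed`,
#'   `n_fp`, `n_sets`, `sensitivity_pct`, `fp_per_set`,
#'   `fp_per_set_rounded`.
#' @export
eval_result <- function(n_true, n_detected, n_fp, n_sets) {
  if (n_detected > n_true)
    stop("n_detected cannot exceed n_true", call. = FALSE)
  structure(
    list(n_true = n_true, n_detected = n_detected,
         n_missed = n_true - n_detected, n_fp = n_fp, n_sets = n_sets,
         sensitivity_pct = 100 * n_detected / n_true,
         fp_per_set = n_fp / n_sets,
         fp_per_set_rounded = round(n_fp / n_sets)),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> %d/%d nodules detected (%.1f%%), %d missed; %d FP over %d sets (%.3f per set, ~%d)\n",
    x$n_detected, x$n_true, x$sensitivity_pct, x$n_missed, x$n_fp,
    x$n_sets, x$fp_per_set, x$fp_per_set_rounded))
  invisible(x)
}

#' Score detections against ground truth
#'
#' A truth nodule counts as detected if a candidate centroid lies within
#' `max(hit_distance_mm, truth radius)` of its center. Matching is greedy
#' by ascending distance (ties broken by descending candidate response),
#' one candidate per truth nodule; unmatched candidates are false
#' positives. Deterministic, and symmetric under permuting the sets.
#'
#' @param candidates_per_set list of candidate frames (one per image set;
#'   see [detect_candidates()]).
#' @param truth_per_set list of truth sets, each a list of [gt_nodule()]
#'   or a data frame with `z_mm, y_mm, x_mm, radius_mm`.
#' @param hit_distance_mm minimum hit radius (mm).
#' @return An `eval_result`, plus a `per_set` attribute with per-set
#'   counts.
#' @export
evaluate <- function(candidates_per_set, truth_per_set, hit_distance_mm = 5) {
  if (length(candidates_per_set) != length(truth_per_set))
    stop("input error: candidates_per_set and truth_per_set lengths differ",
         call. = FALSE)
  if (hit_distance_mm <= 0)
    stop("input error: hit_distance_mm must be > 0", call. = FALSE)
  per_set <- lapply(seq_along(truth_per_set), function(s) {
    .evaluate_one(candidates_per_set[[s]], truth_per_set[[s]],
                  hit_distance_mm)
  })
  res <- eval_result(
    n_true = sum(vapply(per_set, `[[`, numeric(1), "n_true")),
    n_detected = sum(vapply(per_set, `[[`, numeric(1), "n_detected")),
    n_fp = sum(vapply(per_set, `[[`, numeric(1), "n_fp")),
    n_sets = length(truth_per_set)
  )
  attr(res, "per_set") <- per_set
  res
}

.truth_frame <- function(truth) {
  if (is.data.frame(truth)) return(truth)
  data.frame(
    z_mm = vapply(truth, function(n) n$center_mm[1], numeric(1)),
    y_mm = vapply(truth, function(n) n$center_mm[2], numeric(1)),
    x_mm = vapply(truth, function(n) n$center_mm[3], numeric(1)),
    radius_mm = vapply(truth, function(n) n$radius_mm, numeric(1))
  )
}

.evaluate_one <- function(cands, truth, hit_distance_mm) {
  tf <- .truth_frame(truth)
  nt <- nrow(tf)
  nc <- if (is.null(cands)) 0L else nrow(cands)
  if (nt == 0 || nc == 0)
    return(list(n_true = nt, n_detected = 0L, n_fp = nc))
  dz <- outer(cands$z_mm, tf$z_mm, "-")
  dy <- outer(cands$y_mm, tf$y_mm, "-")
  dx <- outer(cands$x_mm, tf$x_mm, "-")
  dd <- sqrt(dz^2 + dy^2 + dx^2)
  lim <- pmax(hit_distance_mm, tf$radius_mm)
  pairs <- which(sweep(dd, 2, lim, "<="), arr.ind = TRUE)
  if (!nrow(pairs))
    return(list(n_true = nt, n_detected = 0L, n_fp = nc))
  pd <- dd[pairs]
  resp <- cands$response[pairs[, 1]]
  ord <- order(pd, -resp, pairs[, 1], pairs[, 2])
  cand_used <- logical(nc)
  truth_hit <- logical(nt)
  for (r in ord) {
    ci <- pairs[r, 1]; ti <- pairs[r, 2]
    if (!cand_used[ci] && !truth_hit[ti]) {
      cand_used[ci] <- TRUE
      truth_hit[ti] <- TRUE
    }
  }
  list(n_true = nt, n_detected = sum(truth_hit), n_fp = sum(!cand_used))
}
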