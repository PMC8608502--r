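#' Rule-based candidate screening model
#'
#' The default false-positive reducer: a candidate is accepted as a nodule
#' only if it passes every rule — minimum equivalent diameter, minimum
#' peak-slice circularity, maximum 3D elongation, and minimum contrast over
#' the surrounding shell. The score is the fraction of rules passed, so a
#' candidate failing one of four rules scores 0.75 but is still labeled
#' with the negative class. Transparent and fully deterministic.
#'
#' @param min_diameter_mm minimum equivalent diameter (mm). The 3 mm
#'   default matches the usual clinical reporting floor for nodules.
#' @param min_circularity minimum peak-slice circularity (dimensionless).
#' @param max_elongation maximum major/minor axis ratio; tubular vessel
#'   fragments score well above spheres here.
#' @param min_contrast_hu minimum region-minus-shell contrast (HU).
#' @param class_names negative and positive class label, in that order.
#' @return A `cad_model` of kind `"rule_based"`.
#' @export
rule_model <- function(min_diameter_mm = 3, min_circularity = 0.5,
                       max_elongation = 2.5, min_contrast_hu = 150,
                       class_names = c("non_nodule", "nodule")) {
  structure(
    list(kind = "rule_based",
         class_names = class_names,
         thresholds = list(min_diameter_mm = min_diameter_mm,
                           min_circularity = min_circularity,
                           max_elongation = max_elongation,
                           min_contrast_hu = min_contrast_hu)),
    class = "cad_model"
  )
}

#' @export
print.cad_model <- function(x, ...) {
  cat(sprintf("<cad_model> kind=%s classes=[%s]\n", x$kind,
              paste(x$class_names, collapse = ", ")))
  if (x$kind == "rule_based") {
    th <- x$thresholds
    cat(sprintf("  rules: diameter >= %.1f mm, circularity >= %.2f, elongation <= %.2f, contrast >= %.0f HU\n",
                th$min_diameter_mm, th$min_circularity, th$max_elongation,
                th$min_contrast_hu))
  } else {
    cat(sprintf("  linear: %d standardized features\n", length(x$weights)))
  }
  invisible(x)
}

#' Fit a linear two-class discriminant on candidate features
#'
#' Fisher's linear discriminant with pooled covariance on z-scored
#' features: the decision value is `w . f_standardized + b`, positive for
#' the second class in `class_names`; the score is its logistic transform.
#' Standardization constants are stored in the model, so the decision is
#' invariant to any affine rescaling of a feature applied consistently at
#' fit and predict time. A degenerate (collinear) pooled covariance is
#' ridge-regularized with a warning.
#'
#' @param features data frame or matrix of numeric features (no missing
#'   values); the `feature_error` column, if present, is dropped.
#' @param labels vector with exactly two classes, >= 2 examples each.
#' @param class_names optional explicit (negative, positive) ordering;
#'   defaults to the sorted unique labels.
#' @return A `cad_model` of kind `"linear"`.
#' @export
fit_classifier <- function(features, labels, class_names = NULL) {
  x <- as.data.frame(features)
  x$feature_error <- NULL
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("features contain missing values", call. = FALSE)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2)
    stop("training error: need exactly 2 classes, got ",
         length(cls), call. = FALSE)
  if (is.null(class_names)) class_names <- cls
  if (!setequal(class_names, cls))
    stop("class_names do not match the labels", call. = FALSE)
  if (min(table(labels)) < 2)
    stop("training error: need >= 2 examples per class", call. = FALSE)

  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  z <- sweep(sweep(x, 2, center, "-"), 2, scale_, "/")
  neg <- z[labels == class_names[1], , drop = FALSE]
  pos <- z[labels == class_names[2], , drop = FALSE]
  mu0 <- colMeans(neg)
  mu1 <- colMeans(pos)
  n0 <- nrow(neg); n1 <- nrow(pos)
  s <- ((n0 - 1) * stats::cov(neg) + (n1 - 1) * stats::cov(pos)) / (n0 + n1 - 2)
  w <- tryCatch(solve(s, mu1 - mu0), error = function(e) NULL)
  if (is.null(w) || rcond(s) < 1e-10) {
    warning("pooled covariance is (near-)singular; ridge-regularizing")
    lam <- 1e-4 * mean(diag(s))
    if (lam <= 0) lam <- 1e-4
    w <- solve(s + diag(lam, ncol(s)), mu1 - mu0)
  }
  b <- -sum(w * (mu0 + mu1) / 2) + log(n1 / n0)
  structure(
    list(kind = "linear", class_names = class_names,
         weights = as.numeric(w), bias = b,
         center = as.numeric(center), scale = as.numeric(scale_),
         feature_names = colnames(x)),
    class = "cad_model"
  )
}

#' Classify candidates from their features
#'
#' Applies a [rule_model()] or a fitted linear discriminant
#' ([fit_classifier()]) to a feature data frame. Rows flagged with
#' `feature_error` get the negative class with score 0.
#'
#' @param features feature data frame from [extract_features()] (or any
#'   frame with the model's feature columns).
#' @param model a `cad_model`.
#' @return Data frame with `label` (from `model$class_names`) and `score`
#'   in \[0, 1\] (rule-based: fraction of rules passed; linear: logistic of
#'   the decision value). Deterministic for fixed inputs.
#' @export
classify_candidates <- function(features, model) {
  f <- as.data.frame(features)
  err <- if ("feature_error" %in% names(f)) f$feature_error else
    rep(FALSE, nrow(f))
  num <- vapply(f, is.numeric, logical(1))
  if (any(num))
    err <- err | rowSums(!is.finite(as.matrix(f[, num, drop = FALSE]))) > 0
  if (model$kind == "rule_based") {
    th <- model$thresholds
    pass <- cbind(f$equivalent_diameter_mm >= th$min_diameter_mm,
                  f$circularity >= th$min_circularity,
                  f$elongation <= th$max_elongation,
                  f$contrast_hu >= th$min_contrast_hu)
    pass[is.na(pass)] <- FALSE
    score <- rowMeans(pass)
    lab <- ifelse(rowSums(pass) == ncol(pass),
                  model$class_names[2], model$class_names[1])
  } else if (model$kind == "linear") {
    missing_ <- setdiff(model$feature_names, names(f))
    if (length(missing_))
      stop("features do not match the model: missing ",
           paste(missing_, collapse = ", "), call. = FALSE)
    x <- as.matrix(f[, model$feature_names, drop = FALSE])
    storage.mode(x) <- "double"
    z <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
    dec <- as.numeric(z %*% model$weights) + model$bias
    score <- stats::plogis(dec)
    lab <- ifelse(dec > 0, model$class_names[2], model$class_names[1])
  } else {
    stop("unknown model kind: ", model$kind, call. = FALSE)
  }
  lab[err] <- model$class_names[1]
  score[err] <- 0
  data.frame(label = lab, score = score, stringsAsFactors = FALSE)
}

#' Save / load a classifier model as JSON
#'
#' Models are persisted as plain JSON (kind, class names, thresholds or
#' weights plus standardization constants) so they are diff-able and
#' editable by hand.
#'
#' @param model a `cad_model`.
#' @param path JSON file path.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$weights)) x$weights <- as.numeric(x$weights)
  structure(x, class = "cad_model")
}
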