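#' Learn a radiality decision boundary from negative-control images
#'
#' Runs unfiltered detection on each negative-control image (where every
#' detection can be assumed a false positive), pools the flatness and
#' integrated-gradient values, and places per-metric percentile cutoffs in
#' the direction that true positives occupy: the lower tail of flatness
#' (true spots are sharper than background features) and the upper tail of
#' integrated gradient (true spots have steeper ring gradients). Percentiles
#' use linear interpolation between order statistics.
#'
#' @param negative_images a matrix, a list of matrices, or a character vector
#'   of TIFF paths.
#' @param config a [detection_config()].
#' @param percentile training percentile in (0, 50); default 5 (cutoffs at
#'   the top 5% in each dimension separately).
#' @param mode `"and"` (default: both criteria must indicate a symmetric
#'   punctum) or `"or"`.
#' @return An object of class `rasp_boundary` with fields `flatness_cutoff`
#'   (accept `<=`), `ig_cutoff` (accept `>=`), `percentile`, `mode`,
#'   `n_training_candidates` and `provenance`.
#' @section Errors: fewer than 20 pooled training candidates, or a constant
#'   metric distribution, raises a validation error (the boundary would be
#'   unreliable).
#' @export
train_boundary <- function(negative_images, config = detection_config(),
                           percentile = 5, mode = c("and", "or")) {
  mode <- match.arg(mode)
  if (percentile <= 0 || percentile >= 50)
    stop_validation("`percentile` must be in (0, 50)")
  if (is.matrix(negative_images)) negative_images <- list(negative_images)
  if (is.character(negative_images)) {
    provenance <- negative_images
    negative_images <- lapply(negative_images, read_image)
  } else {
    provenance <- if (!is.null(names(negative_images))) names(negative_images)
                  else sprintf("image_%d", seq_along(negative_images))
  }
  if (length(negative_images) < 1L)
    stop_validation("at least one negative-control image is required")
  flat <- numeric(0); ig <- numeric(0)
  for (im in negative_images) {
    cand <- detect_puncta(im, config)
    flat <- c(flat, cand$flatness)
    ig <- c(ig, cand$integrated_gradient)
  }
  n <- length(flat)
  if (n < 20L)
    stop_validation(sprintf(
      "only %d training candidate(s) detected; >= 20 required for a reliable boundary", n))
  if (stats::sd(flat) == 0 || stats::sd(ig) == 0)
    stop_validation("degenerate training distribution: a radiality metric is constant")
  structure(list(flatness_cutoff = rasp_quantile(flat, percentile / 100),
                 ig_cutoff = rasp_quantile(ig, 1 - percentile / 100),
                 percentile = percentile, mode = mode,
                 n_training_candidates = n,
                 provenance = as.character(provenance)),
            class = "rasp_boundary")
}

#' Apply a decision boundary to measured candidates
#'
#' Sets `passed_filter` per candidate: under `"and"`, a candidate passes iff
#' `flatness <= flatness_cutoff` and `integrated_gradient >= ig_cutoff`;
#' under `"or"`, either criterion suffices. Candidate order is preserved and
#' no rows are removed, so rejects remain auditable.
#'
#' @param candidates a `rasp_detections` data frame with both metrics present.
#' @param boundary a `rasp_boundary`.
#' @return `candidates` with `passed_filter` updated.
#' @export
apply_boundary <- function(candidates, boundary) {
  if (!inherits(boundary, "rasp_boundary"))
    stop_validation("`boundary` must be a rasp_boundary")
  if (!all(c("flatness", "integrated_gradient") %in% names(candidates)))
    stop_validation("`candidates` lack radiality metrics")
  if (nrow(candidates) == 0L) return(candidates)
  if (any(!is.finite(candidates$flatness)) ||
      any(!is.finite(candidates$integrated_gradient)))
    stop_validation("unmeasured candidate: non-finite radiality metric")
  pass_flat <- candidates$flatness <= boundary$flatness_cutoff
  pass_ig <- candidates$integrated_gradient >= boundary$ig_cutoff
  candidates$passed_filter <- if (boundary$mode == "and") pass_flat & pass_ig
                              else pass_flat | pass_ig
  candidates
}

#' @rdname apply_boundary
#' @param object a `rasp_boundary` (for the `predict` method).
#' @param ... unused.
#' @export
predict.rasp_boundary <- function(object, candidates, ...) {
  apply_boundary(candidates, object)
}

boundary_schema_version <- 1L

#' Save or load a decision boundary as JSON
#'
#' The JSON schema is versioned:
#' `{version, flatness_cutoff, ig_cutoff, percentile, mode,
#' n_training_candidates, provenance[]}`. The round trip is lossless.
#'
#' @param boundary a `rasp_boundary`.
#' @param path file path.
#' @return `save_boundary()` returns `path` invisibly; `load_boundary()`
#'   returns the `rasp_boundary`.
#' @export
save_boundary <- function(boundary, path) {
  if (!inherits(boundary, "rasp_boundary"))
    stop_validation("`boundary` must be a rasp_boundary")
  obj <- c(list(version = boundary_schema_version), unclass(boundary))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_boundary
#' @export
load_boundary <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("boundary file not found: %s", path))
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_io(sprintf("cannot parse boundary JSON: %s",
                                                      conditionMessage(e))))
  required <- c("version", "flatness_cutoff", "ig_cutoff", "percentile",
                "mode", "n_training_candidates")
  missing <- setdiff(required, names(obj))
  if (length(missing) > 0L)
    stop_validation(sprintf("boundary file missing field(s): %s",
                            paste(missing, collapse = ", ")))
  if (!identical(as.integer(obj$version), boundary_schema_version))
    stop_validation(sprintf("unsupported boundary schema version: %s", obj$version))
  if (!obj$mode %in% c("and", "or"))
    stop_validation(sprintf("unknown boundary mode: %s", obj$mode))
  num <- c(obj$flatness_cutoff, obj$ig_cutoff, obj$percentile, obj$n_training_candidates)
  if (!all(is.finite(num))) stop_validation("boundary file has non-finite fields")
  structure(list(flatness_cutoff = as.numeric(obj$flatness_cutoff),
                 ig_cutoff = as.numeric(obj$ig_cutoff),
                 percentile = as.numeric(obj$percentile),
                 mode = obj$mode,
                 n_training_candidates = as.integer(obj$n_training_candidates),
                 provenance = as.character(obj$provenance %||% character(0))),
            class = "rasp_boundary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rasp_boundary <- function(x, ...) {
  cat("rasp decision boundary\n")
  cat(sprintf("  accept if flatness <= %.6g %s integrated gradient >= %.6g\n",
              x$flatness_cutoff, toupper(x$mode), x$ig_cutoff))
  cat(sprintf("  trained at percentile %g on %d candidates from %d image(s)\n",
              x$percentile, x$n_training_candidates, length(x$provenance)))
  invisible(x)
}
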