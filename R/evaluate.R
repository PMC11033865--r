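#' Match detections to ground-truth positions
#'
#' Greedy one-to-one matching: all truth-detection pairs within
#' `match_radius` are considered in order of ascending distance; each truth
#' and each detection is used at most once. Unmatched detections are false
#' positives, unmatched truths false negatives.
#'
#' @param truth,detections `n x 2` matrices (or data frames) of `(row, col)`
#'   positions.
#' @param match_radius maximum pairing distance in px (default 2).
#' @return A list of class `rasp_match`: `tp`, `fp`, `fn`, `pairs` (data
#'   frame `truth_id, detection_id, distance`), `match_radius`.
#' @export
match_detections <- function(truth, detections, match_radius = 2) {
  if (match_radius <= 0) stop_validation("`match_radius` must be positive")
  truth <- as_positions(truth)
  detections <- as_positions(detections)
  nt <- nrow(truth); nd <- nrow(detections)
  pairs <- data.frame(truth_id = integer(), detection_id = integer(),
                      distance = numeric())
  if (nt > 0L && nd > 0L) {
    ord <- order(detections[, 1])
    dr <- detections[ord, 1]; dc <- detections[ord, 2]
    cand_t <- integer(0); cand_d <- integer(0); cand_dist <- numeric(0)
    for (i in seq_len(nt)) {
      lo <- findInterval(truth[i, 1] - match_radius, dr) + 1L
      hi <- findInterval(truth[i, 1] + match_radius, dr)
      if (hi < lo) next
      win <- lo:hi
      dist2 <- (dr[win] - truth[i, 1])^2 + (dc[win] - truth[i, 2])^2
      ok <- dist2 <= match_radius^2
      if (any(ok)) {
        cand_t <- c(cand_t, rep.int(i, sum(ok)))
        cand_d <- c(cand_d, ord[win[ok]])
        cand_dist <- c(cand_dist, sqrt(dist2[ok]))
      }
    }
    if (length(cand_t) > 0L) {
      o <- order(cand_dist, cand_t, cand_d)
      used_t <- logical(nt); used_d <- logical(nd)
      keep <- logical(length(o))
      for (j in o) {
        if (!used_t[cand_t[j]] && !used_d[cand_d[j]]) {
          used_t[cand_t[j]] <- TRUE
          used_d[cand_d[j]] <- TRUE
          keep[j] <- TRUE
        }
      }
      pairs <- data.frame(truth_id = cand_t[keep], detection_id = cand_d[keep],
                          distance = cand_dist[keep])
      pairs <- pairs[order(pairs$truth_id), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  structure(list(tp = nrow(pairs), fp = nd - nrow(pairs), fn = nt - nrow(pairs),
                 pairs = pairs, match_radius = match_radius),
            class = "rasp_match")
}

as_positions <- function(x) {
  if (inherits(x, "rasp_detections"))
    x <- x[x$passed_filter, c("peak_row", "peak_col")]
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(x) || length(x) == 0L) return(matrix(numeric(0), 0L, 2L))
  if (!is.matrix(x) || ncol(x) != 2L)
    stop_validation("positions must be an n x 2 (row, col) matrix")
  x
}

#' Detection scores from a match result
#'
#' `jaccard_index()` returns `tp / (tp + fp + fn)`; `precision()` returns
#' `tp / (tp + fp)` and `sensitivity()` `tp / (tp + fn)` (1 when their
#' denominator is 0 and there is nothing to find or nothing found wrongly).
#'
#' @param match a `rasp_match` from [match_detections()].
#' @return A single number in `[0, 1]`.
#' @export
jaccard_index <- function(match) {
  n <- match$tp + match$fp + match$fn
  if (n == 0L) stop_validation("jaccard index undefined: no truths or detections")
  match$tp / n
}

#' @rdname jaccard_index
#' @export
precision <- function(match) {
  if (match$tp + match$fp == 0L) return(1)
  match$tp / (match$tp + match$fp)
}

#' @rdname jaccard_index
#' @export
sensitivity <- function(match) {
  if (match$tp + match$fn == 0L) return(1)
  match$tp / (match$tp + match$fn)
}

#' @export
print.rasp_match <- function(x, ...) {
  cat(sprintf("rasp match (radius %g px): tp %d, fp %d, fn %d; jaccard %.4f\n",
              x$match_radius, x$tp, x$fp, x$fn,
              if (x$tp + x$fp + x$fn > 0) jaccard_index(x) else NA_real_))
  invisible(x)
}

#' Contrast-to-noise ratio
#'
#' `(signal_peak - mean(background)) / sd(background)`, with the sample
#' (n - 1) standard deviation. The CNR is invariant under adding a constant
#' to the whole image and under multiplicative rescaling.
#'
#' @param image numeric matrix.
#' @param signal_peak the signal maximum `S_A` (same units as the image).
#' @param background_region logical mask or index vector/matrix selecting the
#'   background pixels (at least 2, with nonzero variance).
#' @return Dimensionless CNR.
#' @export
cnr <- function(image, signal_peak, background_region) {
  check_image(image)
  if (is.matrix(background_region) && is.logical(background_region))
    background_region <- which(background_region)
  else if (is.matrix(background_region))
    background_region <- background_region[, 1] + (background_region[, 2] - 1L) * nrow(image)
  bg <- image[background_region]
  if (length(bg) < 2L) stop_validation("background region needs >= 2 pixels")
  s <- stats::sd(bg)
  if (s == 0) stop_validation("background region has zero variance")
  (signal_peak - mean(bg)) / s
}

#' Benchmark a detector over a CNR scene series
#'
#' Runs `detector` on every scene of a [scene_series_by_cnr()] series and
#' scores it against the scene ground truth. The detector is pluggable so
#' third-party position lists can be benchmarked through the same harness:
#' it is called as `detector(image)` and must return either an `n x 2`
#' `(row, col)` position matrix or a `rasp_detections` frame (only
#' candidates with `passed_filter` are scored).
#'
#' @param scenes list of `rasp_scene` objects.
#' @param detector detection callable; defaults to [detect_puncta()] with
#'   `config` and `boundary`.
#' @param boundary optional `rasp_boundary` for the default detector.
#' @param config [detection_config()] for the default detector.
#' @param match_radius matching radius in px.
#' @param detector_name label written into the report.
#' @return Data frame with one row per scene: `cnr`, `tp`, `fp`, `fn`,
#'   `jaccard`, `precision`, `sensitivity`, `n_truth`, `n_detected`,
#'   `detector_name`.
#' @export
cnr_sweep_report <- function(scenes, detector = NULL, boundary = NULL,
                             config = detection_config(), match_radius = 2,
                             detector_name = NULL) {
  if (is.null(detector)) {
    detector <- function(image) detect_puncta(image, config, boundary)
    if (is.null(detector_name))
      detector_name <- if (is.null(boundary)) "rasp_unfiltered" else "rasp"
  }
  if (is.null(detector_name)) detector_name <- "custom"
  rows <- lapply(scenes, function(sc) {
    if (!inherits(sc, "rasp_scene")) stop_validation("`scenes` must be rasp_scene objects")
    truth_pos <- cbind(sc$truth$y0, sc$truth$x0)
    det <- detector(sc$image)
    m <- match_detections(truth_pos, as_positions(det), match_radius)
    data.frame(cnr = mean(sc$truth$cnr_true, na.rm = TRUE),
               tp = m$tp, fp = m$fp, fn = m$fn,
               jaccard = jaccard_index(m), precision = precision(m),
               sensitivity = sensitivity(m), n_truth = nrow(sc$truth),
               n_detected = m$tp + m$fp, detector_name = detector_name)
  })
  do.call(rbind, rows)
}
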