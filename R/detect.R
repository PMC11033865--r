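#' Detection pipeline configuration
#'
#' Parameters of the candidate-detection pipeline. Defaults follow the
#' published pipeline: high-pass by subtraction of a sigma = 1.4 px Gaussian
#' blur, Laplacian-of-Gaussian enhancement at sigma = 2 px, retention of the
#' top 5% brightest enhanced pixels, and radiality metrics on a radius-2
#' pixel ring.
#'
#' @param highpass_sigma Gaussian blur sigma (px) for the high-pass step.
#' @param log_sigma Laplacian-of-Gaussian sigma (px).
#' @param threshold_percent percentage of brightest enhanced pixels kept.
#' @param ring_radius radius (px) of the radiality ring.
#' @param min_area,max_area object area limits (px^2) applied to candidates.
#' @param annulus annulus `c(inner, outer)` of Chebyshev distances (px) from
#'   the peak used for the local background estimate.
#' @return An object of class `rasp_config`.
#' @export
detection_config <- function(highpass_sigma = 1.4, log_sigma = 2,
                             threshold_percent = 5, ring_radius = 2L,
                             min_area = 1L, max_area = Inf,
                             annulus = c(3L, 5L)) {
  if (highpass_sigma <= 0 || log_sigma <= 0)
    stop_validation("sigmas must be positive")
  if (threshold_percent <= 0 || threshold_percent >= 100)
    stop_validation("`threshold_percent` must be in (0, 100)")
  ring_radius <- as.integer(ring_radius)
  if (ring_radius < 1L) stop_validation("`ring_radius` must be >= 1")
  if (min_area < 1) stop_validation("`min_area` must be >= 1")
  if (max_area < min_area) stop_validation("`max_area` must be >= `min_area`")
  annulus <- as.integer(annulus)
  if (length(annulus) != 2L || annulus[1] < ring_radius || annulus[2] <= annulus[1])
    stop_validation("`annulus` must be c(inner, outer) with inner >= ring_radius, outer > inner")
  structure(list(highpass_sigma = highpass_sigma, log_sigma = log_sigma,
                 threshold_percent = threshold_percent,
                 ring_radius = ring_radius, min_area = min_area,
                 max_area = max_area, annulus = annulus),
            class = "rasp_config")
}

#' Feature enhancement for punctum detection
#'
#' High-pass filters the image by subtracting its Gaussian blur, then applies
#' a negated Laplacian-of-Gaussian so that Gaussian-shaped spots become
#' bright maxima. Both filters use reflect padding at the borders; the LoG
#' kernel is adjusted to zero sum, so constant images map to zero exactly.
#'
#' @param image numeric matrix of finite intensities.
#' @param config a [detection_config()].
#' @return Enhanced image, same shape as the input.
#' @export
enhance <- function(image, config = detection_config()) {
  check_image(image, min_dim = 3L)
  if (!all(is.finite(image))) stop_validation("`image` contains non-finite pixels")
  highpass <- image - convolve2(image, gaussian_kernel(config$highpass_sigma))
  -convolve2(highpass, log_kernel(config$log_sigma))
}

#' Threshold the brightest pixels of an enhanced image
#'
#' Keeps the pixels at or above the `(100 - threshold_percent)`-th percentile
#' of the enhanced image (top `threshold_percent`% brightest); ties at the
#' percentile value are all kept. A constant image is degenerate: every pixel
#' ties, all are kept, and a warning is emitted.
#'
#' @param enhanced numeric matrix from [enhance()].
#' @param threshold_percent percentage of brightest pixels to keep.
#' @return Logical matrix of the same shape.
#' @export
threshold_mask <- function(enhanced, threshold_percent = 5) {
  check_image(enhanced, arg = "enhanced")
  if (!all(is.finite(enhanced))) stop_validation("`enhanced` contains non-finite pixels")
  if (threshold_percent <= 0 || threshold_percent >= 100)
    stop_validation("`threshold_percent` must be in (0, 100)")
  rng <- range(enhanced)
  if (rng[1] == rng[2]) {
    warning("degenerate threshold: enhanced image is constant; keeping all pixels")
    return(matrix(TRUE, nrow(enhanced), ncol(enhanced)))
  }
  thr <- rasp_quantile(enhanced, 1 - threshold_percent / 100)
  enhanced >= thr
}

#' Extract and measure punctum candidates from a binary mask
#'
#' Labels 8-connected components of `mask`, measures each against the raw
#' image, and returns one row per surviving candidate. Per candidate the peak
#' pixel is the argmax of the raw image over the component (ties broken by
#' lowest `(row, col)` in lexicographic order); flatness and integrated
#' gradient are evaluated on the ring of `config$ring_radius` around the peak
#' in the raw image; the local background is the mean raw intensity over the
#' configured annulus and the sum intensity is the background-corrected sum
#' over the component pixels. Candidates whose ring leaves the image, whose
#' peak intensity is not positive, or whose area falls outside
#' `[min_area, max_area]` are dropped (counts are kept in attributes).
#'
#' @param image raw image (numeric matrix).
#' @param mask logical or 0/1 matrix, same shape.
#' @param config a [detection_config()].
#' @return A `data.frame` of class `rasp_detections` with columns `label`,
#'   `peak_row`, `peak_col`, `centroid_row`, `centroid_col`, `area`,
#'   `flatness`, `integrated_gradient`, `sum_intensity`, `local_background`,
#'   `passed_filter` (all `TRUE` until a boundary is applied). Attributes
#'   `n_edge_dropped`, `n_area_dropped`, `n_peak_dropped` count the discards;
#'   attribute `pixel_sets` holds each candidate's component pixel indices.
#' @export
extract_candidates <- function(image, mask, config = detection_config()) {
  check_image(image)
  if (!identical(dim(image), dim(mask)))
    stop_validation("`mask` and `image` shapes differ")
  lab <- label_components(mask)
  empty <- candidate_frame()
  if (max(lab) == 0L)
    return(as_detections(empty, list(), dim(image), config, 0L, 0L, 0L))

  nr <- nrow(image)
  idx <- which(lab > 0L)
  l <- lab[idx]
  v <- image[idx]
  pr <- ((idx - 1L) %% nr) + 1L
  pc <- ((idx - 1L) %/% nr) + 1L
  k <- max(l)
  area <- tabulate(l, k)
  csum <- as.numeric(rowsum(v, l))
  crow <- as.numeric(rowsum(pr, l)) / area
  ccol <- as.numeric(rowsum(pc, l)) / area
  ord <- order(l, -v, pr, pc)
  first <- ord[!duplicated(l[ord])]
  peak_r <- pr[first]; peak_c <- pc[first]; peak_v <- v[first]
  pixel_sets <- split(idx, l)

  keep_area <- area >= config$min_area & area <= config$max_area
  n_area <- sum(!keep_area)
  r <- config$ring_radius
  in_bounds <- peak_r > r & peak_r <= nr - r & peak_c > r & peak_c <= ncol(image) - r
  n_edge <- sum(keep_area & !in_bounds)
  pos_peak <- peak_v > 0
  n_peak <- sum(keep_area & in_bounds & !pos_peak)
  keep <- keep_area & in_bounds & pos_peak
  if (!any(keep))
    return(as_detections(empty, list(), dim(image), config, n_edge, n_area, n_peak))

  sel <- which(keep)
  off <- ring_offsets(r)
  ring_lin <- outer(peak_r[sel], off[, 1], "+") +
    (outer(peak_c[sel], off[, 2], "+") - 1L) * nr
  ring_vals <- matrix(image[ring_lin], nrow = length(sel))
  flat <- rowMeans(ring_vals) / peak_v[sel]
  gmag <- gradient_field(image)$gmag
  ig <- rowSums(matrix(gmag[ring_lin], nrow = length(sel)))
  bg <- annulus_background(image, peak_r[sel], peak_c[sel], config$annulus)
  sum_int <- csum[sel] - bg * area[sel]

  out <- data.frame(label = seq_along(sel), peak_row = peak_r[sel],
                    peak_col = peak_c[sel], centroid_row = crow[sel],
                    centroid_col = ccol[sel], area = area[sel],
                    flatness = flat, integrated_gradient = ig,
                    sum_intensity = sum_int, local_background = bg,
                    passed_filter = TRUE)
  as_detections(out, unname(pixel_sets[sel]), dim(image), config,
                n_edge, n_area, n_peak)
}

candidate_frame <- function() {
  data.frame(label = integer(), peak_row = integer(), peak_col = integer(),
             centroid_row = numeric(), centroid_col = numeric(),
             area = integer(), flatness = numeric(),
             integrated_gradient = numeric(), sum_intensity = numeric(),
             local_background = numeric(), passed_filter = logical())
}

as_detections <- function(df, pixel_sets, image_dim, config,
                          n_edge, n_area, n_peak) {
  structure(df, pixel_sets = pixel_sets, image_dim = image_dim,
            config = config, n_edge_dropped = as.integer(n_edge),
            n_area_dropped = as.integer(n_area),
            n_peak_dropped = as.integer(n_peak),
            class = c("rasp_detections", "data.frame"))
}

# Mean raw intensity over a Chebyshev annulus [inner, outer] around each
# peak, clipped to the image; vectorized over candidates.
annulus_background <- function(image, peak_r, peak_c, annulus) {
  nr <- nrow(image); nc <- ncol(image)
  o <- annulus[2]
  g <- expand.grid(dr = -o:o, dc = -o:o)
  cheb <- pmax(abs(g$dr), abs(g$dc))
  g <- g[cheb >= annulus[1] & cheb <= annulus[2], ]
  rr <- outer(peak_r, g$dr, "+")
  cc <- outer(peak_c, g$dc, "+")
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  lin <- pmin(pmax(rr, 1L), nr) + (pmin(pmax(cc, 1L), nc) - 1L) * nr
  vals <- matrix(image[lin], nrow = length(peak_r))
  vals[!ok] <- NA_real_
  rowMeans(vals, na.rm = TRUE)
}

#' Sum intensity and local background of one candidate
#'
#' Local background is the mean raw intensity over the pixels at Chebyshev
#' distance in `[annulus[1], annulus[2]]` from `peak_pixel` (clipped to the
#' image); the sum intensity is the raw sum over the candidate's component
#' pixels minus background times area. This is the fast per-spot estimator
#' used in place of Gaussian fitting.
#'
#' @param image raw image.
#' @param pixels component pixel coordinates, an `n x 2` `(row, col)` matrix
#'   (or a vector of linear indices into `image`).
#' @param peak_pixel `c(row, col)` of the candidate's raw-image maximum.
#' @param annulus `c(inner, outer)` Chebyshev distances in px.
#' @return `list(sum_intensity =, local_background =)`.
#' @export
estimate_intensity_background <- function(image, pixels, peak_pixel,
                                          annulus = c(3L, 5L)) {
  check_image(image)
  annulus <- as.integer(annulus)
  if (length(annulus) != 2L || annulus[2] <= annulus[1] || annulus[1] < 1L)
    stop_validation("`annulus` must be c(inner, outer) with outer > inner >= 1")
  if (is.matrix(pixels)) pixels <- pixels[, 1] + (pixels[, 2] - 1L) * nrow(image)
  peak_pixel <- as.integer(peak_pixel)
  nr <- nrow(image); nc <- ncol(image)
  if (peak_pixel[1] + annulus[1] < 1L || peak_pixel[1] - annulus[1] > nr ||
      peak_pixel[2] + annulus[1] < 1L || peak_pixel[2] - annulus[1] > nc)
    stop_validation("annulus lies fully outside the image")
  bg <- annulus_background(image, peak_pixel[1], peak_pixel[2], annulus)
  list(sum_intensity = sum(image[pixels]) - bg * length(pixels),
       local_background = bg)
}

#' Detect puncta in an image
#'
#' The full candidate pipeline: [enhance()], [threshold_mask()],
#' [extract_candidates()], then — when a decision boundary is supplied —
#' [apply_boundary()]. All candidates are returned with their
#' `passed_filter` flags so rejected objects can be audited; subset on
#' `passed_filter` for the accepted puncta.
#'
#' @param image raw image (numeric matrix).
#' @param config a [detection_config()].
#' @param boundary optional [train_boundary()] result; `NULL` returns
#'   unfiltered candidates (all flagged `TRUE`).
#' @return A `rasp_detections` data frame (see [extract_candidates()]).
#' @examples
#' set.seed(1)
#' img <- matrix(rpois(128 * 128, 50), 128, 128)
#' det <- detect_puncta(img)
#' nrow(det)
#' @export
detect_puncta <- function(image, config = detection_config(), boundary = NULL) {
  enhanced <- enhance(image, config)
  mask <- threshold_mask(enhanced, config$threshold_percent)
  cand <- extract_candidates(image, mask, config)
  if (!is.null(boundary)) cand <- apply_boundary(cand, boundary)
  cand
}

#' @export
print.rasp_detections <- function(x, ...) {
  cat(sprintf("rasp detections: %d candidate(s), %d passed filter\n",
              nrow(x), sum(x$passed_filter)))
  cat(sprintf("  dropped: %d edge, %d area, %d non-positive peak\n",
              attr(x, "n_edge_dropped"), attr(x, "n_area_dropped"),
              attr(x, "n_peak_dropped")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}
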