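#' Pixel ring around a candidate punctum
#'
#' Returns the ordered set of pixels at Chebyshev distance exactly
#' `radius_px` from `center`, i.e. the perimeter of the
#' `(2*radius_px + 1)`-square window centered there (16 pixels at the default
#' radius 2). This ring is the support on which both radiality metrics —
#' [flatness()] and [integrated_gradient()] — are evaluated. The default
#' radius of 2 px matches the outer radius of a diffraction-limited spot when
#' the point-spread function is sampled at about twice the pixel size, and
#' should be recalibrated for other magnifications.
#'
#' @param center integer vector `c(row, col)`, 1-based, inside the image.
#' @param radius_px ring radius in pixels (integer, >= 1).
#' @param image_shape integer vector `c(rows, cols)`.
#' @return A list of class `rasp_ring` with elements `center`, `radius_px`,
#'   `ring_pixels` (an `n x 2` matrix of `(row, col)` coordinates, ordered
#'   clockwise from the top-left corner) and `n = 8 * radius_px`.
#' @section Errors: a ring that leaves the image raises an error of class
#'   `rasp_edge_candidate`; callers discard such edge candidates.
#' @examples
#' ring_coordinates(c(10, 10), 2, c(21, 21))$n  # 16
#' @export
ring_coordinates <- function(center, radius_px = 2L, image_shape) {
  r <- as.integer(radius_px)
  if (length(r) != 1L || is.na(r) || r < 1L)
    stop_validation("`radius_px` must be a single integer >= 1")
  center <- as.integer(center)
  if (length(center) != 2L || any(is.na(center)))
    stop_validation("`center` must be c(row, col)")
  image_shape <- as.integer(image_shape)
  if (any(center < 1L) || center[1] > image_shape[1] || center[2] > image_shape[2])
    stop_validation("`center` must lie inside the image")
  off <- ring_offsets(r)
  px <- cbind(row = center[1] + off[, 1], col = center[2] + off[, 2])
  if (any(px[, 1] < 1L | px[, 1] > image_shape[1] |
          px[, 2] < 1L | px[, 2] > image_shape[2]))
    stop_rasp(sprintf("ring of radius %d at (%d, %d) leaves the image: edge candidate",
                      r, center[1], center[2]), "rasp_edge_candidate")
  structure(list(center = center, radius_px = r, ring_pixels = px,
                 n = nrow(px)),
            class = "rasp_ring")
}

# Ordered Chebyshev ring offsets: top edge left->right, right edge
# top->bottom, bottom edge right->left, left edge bottom->top.
ring_offsets <- function(r) {
  top    <- cbind(-r, seq(-r, r))
  right  <- cbind(seq(-r + 1L, r), r)
  bottom <- cbind(r, seq(r - 1L, -r))
  left   <- cbind(seq(r - 1L, -r + 1L), -r)
  off <- rbind(top, right, bottom, left)
  storage.mode(off) <- "integer"
  dimnames(off) <- NULL
  off
}

#' Flatness of a candidate punctum
#'
#' Mean intensity over the ring pixels divided by the intensity at the ring
#' center (the candidate's local maximum), both read from the raw image. A
#' sharply peaked, diffraction-limited spot has low flatness (the ring sits on
#' the decaying flank of the point-spread function), whereas a broad
#' autofluorescent feature has flatness near 1. The metric is invariant under
#' multiplicative rescaling of the image but not under additive offsets.
#'
#' @param image numeric matrix (raw, unfiltered intensities).
#' @param ring a `rasp_ring` from [ring_coordinates()].
#' @return The dimensionless flatness ratio.
#' @section Errors: a non-positive center intensity raises an error of class
#'   `rasp_undefined_flatness` (the candidate is rejected).
#' @export
flatness <- function(image, ring) {
  check_image(image)
  i_max <- image[ring$center[1], ring$center[2]]
  if (!is.finite(i_max) || i_max <= 0)
    stop_rasp("flatness undefined: center intensity is not positive",
              "rasp_undefined_flatness")
  mean(image[ring$ring_pixels]) / i_max
}

#' Per-pixel gradient field of an image
#'
#' Gradients along x (columns) and y (rows) by central differences in the
#' interior and one-sided differences at the borders, plus the pointwise
#' gradient magnitude `sqrt(gx^2 + gy^2)`. This is the minimal consistent
#' stencil; it is exact for affine images.
#'
#' @param image numeric matrix, at least 3x3.
#' @return A list of class `rasp_gradient_field` with matrices `gx`, `gy`,
#'   `gmag`, all the shape of `image`.
#' @export
gradient_field <- function(image) {
  check_image(image, min_dim = 3L)
  nr <- nrow(image); nc <- ncol(image)
  gx <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (image[, 3:nc] - image[, 1:(nc - 2)]) / 2
  gx[, 1] <- image[, 2] - image[, 1]
  gx[, nc] <- image[, nc] - image[, nc - 1]
  gy <- matrix(0, nr, nc)
  gy[2:(nr - 1), ] <- (image[3:nr, ] - image[1:(nr - 2), ]) / 2
  gy[1, ] <- image[2, ] - image[1, ]
  gy[nr, ] <- image[nr, ] - image[nr - 1, ]
  structure(list(gx = gx, gy = gy, gmag = sqrt(gx^2 + gy^2)),
            class = "rasp_gradient_field")
}

#' Integrated gradient of a candidate punctum
#'
#' Sum of gradient magnitudes over the ring pixels. A radially symmetric
#' punctum places the steep flank of its point-spread function on the ring,
#' so true spots score high; flat background and single-pixel noise spikes
#' score low. The metric is homogeneous of degree 1 in the image intensities
#' and invariant under additive offsets.
#'
#' @param gfield a `rasp_gradient_field` from [gradient_field()].
#' @param ring a `rasp_ring` from [ring_coordinates()].
#' @return Sum of `gmag` over the ring (intensity units per pixel).
#' @export
integrated_gradient <- function(gfield, ring) {
  if (!inherits(gfield, "rasp_gradient_field"))
    stop_validation("`gfield` must come from gradient_field()")
  sum(gfield$gmag[ring$ring_pixels])
}
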