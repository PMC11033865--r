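#' Per-pixel photon-transfer calibration of an sCMOS camera
#'
#' From a photon-transfer series — one dark stack plus stacks at several
#' uniform illumination levels — estimates, per pixel, the camera offset
#' (mean of the dark stack, in counts) and the gain in photoelectrons per
#' count. Across the illumination levels the shot-noise variance of a pixel
#' grows linearly with its offset-subtracted mean: an ordinary least-squares
#' fit (with intercept, which absorbs read noise) of variance against
#' offset-subtracted mean gives a slope in counts per photoelectron, and the
#' gain is its reciprocal. Pixels with a non-positive or non-finite slope
#' are flagged invalid.
#'
#' @param dark_stack 3D array `rows x cols x frames` recorded with no
#'   illumination.
#' @param level_stacks list of 3D arrays (same pixel shape), one per
#'   illumination level; at least 3 levels, at least 100 frames per stack.
#' @return An object of class `rasp_calibration` with matrices `offset`
#'   (counts) and `gain` (photoelectrons per count; `NA` where invalid),
#'   logical matrix `valid`, and fields `n_levels`, `frames_per_level`.
#' @export
estimate_calibration <- function(dark_stack, level_stacks) {
  if (!is.array(dark_stack) || length(dim(dark_stack)) != 3L)
    stop_validation("`dark_stack` must be a rows x cols x frames array")
  if (!is.list(level_stacks) || length(level_stacks) < 3L)
    stop_validation("gain estimation requires >= 3 illumination levels (plus the dark stack)")
  shape <- dim(dark_stack)[1:2]
  frames <- c(dim(dark_stack)[3],
              vapply(level_stacks, function(s) dim(s)[3], numeric(1)))
  if (any(frames < 100L))
    stop_validation("each stack needs >= 100 frames")
  for (s in level_stacks)
    if (!is.array(s) || length(dim(s)) != 3L || !identical(dim(s)[1:2], shape))
      stop_validation("all stacks must share the camera pixel shape")

  offset <- rowMeans(dark_stack, dims = 2L)
  npx <- prod(shape)
  nlev <- length(level_stacks)
  mu <- matrix(0, npx, nlev)
  va <- matrix(0, npx, nlev)
  for (j in seq_len(nlev)) {
    s <- level_stacks[[j]]
    nf <- dim(s)[3]
    m <- rowMeans(s, dims = 2L)
    m2 <- rowMeans(s^2, dims = 2L)
    mu[, j] <- m - offset
    va[, j] <- (m2 - m^2) * nf / (nf - 1)
  }
  if (max(mu) == min(mu))
    stop_validation("all illumination levels are identical; cannot fit a slope")
  mx <- rowMeans(mu)
  my <- rowMeans(va)
  sxx <- rowSums((mu - mx)^2)
  if (max(sxx) == 0)
    stop_validation("all illumination levels are identical per pixel; cannot fit a slope")
  sxy <- rowSums((mu - mx) * (va - my))
  slope <- sxy / sxx
  valid <- is.finite(slope) & slope > 0
  gain <- ifelse(valid, 1 / slope, NA_real_)
  structure(list(offset = matrix(offset, shape[1], shape[2]),
                 gain = matrix(gain, shape[1], shape[2]),
                 valid = matrix(valid, shape[1], shape[2]),
                 n_levels = nlev, frames_per_level = dim(level_stacks[[1]])[3]),
            class = "rasp_calibration")
}

#' Convert camera counts to photons
#'
#' `photons = (counts - offset) * gain` per pixel, clipped at zero; pixels
#' flagged invalid in the calibration propagate as `NA`.
#'
#' @param image counts matrix, camera-shaped.
#' @param cal a [estimate_calibration()] result.
#' @return Photon matrix, same shape.
#' @export
counts_to_photons <- function(image, cal) {
  check_image(image)
  if (!inherits(cal, "rasp_calibration"))
    stop_validation("`cal` must be a rasp_calibration")
  if (!identical(dim(image), dim(cal$offset)))
    stop_validation("image and calibration shapes differ")
  out <- pmax((image - cal$offset) * cal$gain, 0)
  out[!cal$valid] <- NA_real_
  out
}

#' @export
print.rasp_calibration <- function(x, ...) {
  cat(sprintf("rasp camera calibration: %dx%d px, %d levels x %d frames\n",
              nrow(x$offset), ncol(x$offset), x$n_levels, x$frames_per_level))
  cat(sprintf("  offset median %.2f counts; gain median %.4f e-/count; %d invalid pixel(s)\n",
              stats::median(x$offset), stats::median(x$gain, na.rm = TRUE),
              sum(!x$valid)))
  invisible(x)
}

#' Simulate a photon-transfer series
#'
#' Camera model used for calibration validation: at illumination level
#' `lambda`, each pixel records
#' `counts = offset + Poisson(lambda) / gain + read noise`, with per-pixel
#' `gain` (photoelectrons per count) and `offset` (counts). Serves as the
#' ground-truthed input for [estimate_calibration()] round trips.
#'
#' @param gain,offset scalars or camera-shaped matrices.
#' @param shape camera shape `c(rows, cols)`.
#' @param photon_levels vector of mean photoelectron counts, one per
#'   illumination level (0 entries are allowed but the dark stack is always
#'   generated separately).
#' @param n_frames frames per stack.
#' @param read_noise_sd Gaussian read noise sd in counts.
#' @param rng_seed seed.
#' @return `list(dark = array, levels = list of arrays)`.
#' @export
simulate_photon_transfer <- function(gain, offset, shape = c(16L, 16L),
                                     photon_levels = 100 * 2^(0:6),
                                     n_frames = 1000L, read_noise_sd = 1,
                                     rng_seed = NULL) {
  shape <- as.integer(shape)
  npx <- prod(shape)
  gain <- matrix(gain, shape[1], shape[2])
  offset <- matrix(offset, shape[1], shape[2])
  make_stack <- function(lambda) {
    counts <- offset[rep(seq_len(npx), n_frames)] +
      stats::rpois(npx * n_frames, lambda) / gain[rep(seq_len(npx), n_frames)] +
      stats::rnorm(npx * n_frames, sd = read_noise_sd)
    array(counts, c(shape, n_frames))
  }
  with_seed(rng_seed, list(
    dark = make_stack(0),
    levels = lapply(photon_levels, make_stack)))
}
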