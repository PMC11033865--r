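# Ground-truthed scene simulator: 2D Gaussian puncta with Poisson shot
# noise, large irregular aggregates inserted via a distance-transform
# sigmoid, and a structured-background generator. Images are photon-count
# matrices; positions are 1-based with x along columns and y along rows.

# Render Gaussian spots A * exp(-((x-x0)^2 + (y-y0)^2) / (2 sigma^2)) onto a
# blank image; per spot, an Otsu mask of the isolated spot patch records the
# pixels the punctum covers. Returns the noiseless image plus bookkeeping.
render_spots <- function(shape, x0, y0, amplitude, sigma) {
  nr <- shape[1]; nc <- shape[2]
  img <- matrix(0, nr, nc)
  n <- length(x0)
  masks <- vector("list", n)
  peak_true <- numeric(n)
  sum_true <- numeric(n)
  w <- ceiling(5 * sigma)
  for (i in seq_len(n)) {
    rows <- max(1L, floor(y0[i]) - w):min(nr, ceiling(y0[i]) + w)
    cols <- max(1L, floor(x0[i]) - w):min(nc, ceiling(x0[i]) + w)
    patch <- amplitude * exp(-(outer((rows - y0[i])^2, (cols - x0[i])^2, "+")) /
                               (2 * sigma^2))
    img[rows, cols] <- img[rows, cols] + patch
    if (amplitude > 0) {
      thr <- amplitude * EBImage::otsu(patch / amplitude)
      sel <- which(patch > thr)
      pr <- rows[((sel - 1L) %% length(rows)) + 1L]
      pc <- cols[((sel - 1L) %/% length(rows)) + 1L]
      masks[[i]] <- pr + (pc - 1L) * nr
      peak_true[i] <- max(patch[sel])
      sum_true[i] <- sum(patch[sel])
    } else {
      masks[[i]] <- integer(0)
    }
  }
  list(image = img, masks = masks, peak_true = peak_true, sum_true = sum_true)
}

#' Render a field of simulated diffraction-limited puncta
#'
#' Places `n_puncta` 2D Gaussian puncta of equal amplitude onto a blank
#' image, either on a regular grid or uniformly at random; in both modes a
#' minimum center separation of `6 * sigma` is enforced so ground-truth spots
#' stay resolvable. Alongside the noiseless image, a per-punctum binary mask
#' (Otsu's threshold applied to the isolated rendered spot) records the
#' pixels each punctum covers, with its true summed intensity and peak value.
#'
#' @param shape image shape `c(rows, cols)`.
#' @param n_puncta number of puncta.
#' @param amplitude peak amplitude `A` (photons) of every punctum.
#' @param sigma punctum width in px (1.4 is typical for spinning-disk
#'   confocal data, 1.2 for widefield).
#' @param arrangement `"grid"` (deterministic, seed-independent positions)
#'   or `"uniform_random"`.
#' @param rng_seed seed for random placement.
#' @return A list of class `rasp_puncta`: `image` (noiseless render), `truth`
#'   (data frame `id, x0, y0, amplitude, sigma, peak_true,
#'   sum_intensity_true`), and `masks` (list of linear pixel index vectors).
#' @export
render_puncta_grid <- function(shape, n_puncta, amplitude, sigma = 1.4,
                               arrangement = c("grid", "uniform_random"),
                               rng_seed = NULL) {
  arrangement <- match.arg(arrangement)
  shape <- as.integer(shape)
  if (n_puncta < 0) stop_validation("`n_puncta` must be >= 0")
  if (sigma <= 0) stop_validation("`sigma` must be positive")
  if (amplitude < 0) stop_validation("`amplitude` must be >= 0")
  sep <- 6 * sigma
  margin <- ceiling(3 * sigma) + 3
  if (n_puncta == 0L) {
    pos <- cbind(x = numeric(0), y = numeric(0))
  } else if (arrangement == "grid") {
    k <- ceiling(sqrt(n_puncta))
    sr <- (shape[1] - 2 * margin) / k
    sc <- (shape[2] - 2 * margin) / k
    if (min(sr, sc) < sep)
      stop_validation(sprintf(
        "n_puncta = %d too large for a %dx%d grid at >= 6 sigma separation",
        n_puncta, shape[1], shape[2]))
    g <- expand.grid(i = seq_len(k), j = seq_len(k))[seq_len(n_puncta), ]
    pos <- cbind(x = margin + (g$j - 0.5) * sc, y = margin + (g$i - 0.5) * sr)
  } else {
    pos <- with_seed(rng_seed, sample_separated(shape, n_puncta, sep, margin))
  }
  sp <- render_spots(shape, pos[, 1], pos[, 2], amplitude, sigma)
  truth <- data.frame(id = seq_len(n_puncta), x0 = pos[, 1], y0 = pos[, 2],
                      amplitude = amplitude, sigma = sigma,
                      peak_true = sp$peak_true,
                      sum_intensity_true = sp$sum_true)
  structure(list(image = sp$image, truth = truth, masks = sp$masks),
            class = "rasp_puncta")
}

sample_separated <- function(shape, n, sep, margin) {
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 10000L * n
  sep2 <- sep^2
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop_validation(sprintf(
        "could not place %d puncta at >= %.1f px separation (placed %d)",
        n, sep, placed))
    x <- stats::runif(1, margin, shape[2] - margin)
    y <- stats::runif(1, margin, shape[1] - margin)
    if (placed == 0L ||
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >= sep2) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
  }
  cbind(x = xs, y = ys)
}

#' Apply Poisson shot noise to a photon-count image
#'
#' Each pixel is replaced by an independent Poisson draw with mean equal to
#' the pixel value. Reproducible under a fixed seed.
#'
#' @param image nonnegative numeric matrix (interpreted as photons).
#' @param rng_seed seed.
#' @return Integer-valued matrix of the same shape.
#' @export
add_poisson_noise <- function(image, rng_seed = NULL) {
  check_image(image)
  if (any(image < 0)) stop_validation("Poisson noise requires nonnegative input")
  with_seed(rng_seed,
            matrix(stats::rpois(length(image), image), nrow(image), ncol(image)))
}

#' Prepare a large-aggregate insert
#'
#' Turns a cropped aggregate region of interest into an insert for scene
#' composition. The aggregate footprint is Otsu's threshold of the ROI; every
#' background pixel gets its Euclidean distance `d` to the nearest aggregate
#' pixel; the ROI is multiplied by the sigmoid correction
#' `c = 2 / (1 + exp(d / a))` (equal to 1 on the aggregate, decaying with
#' length scale `a`), which suppresses the structured background in the crop
#' while keeping the aggregate signal; finally the corrected crop is
#' zero-padded to `target_shape` at a seeded random offset.
#'
#' @param roi numeric matrix, the cropped aggregate ROI.
#' @param a sigmoid decay scale in px (default 10).
#' @param target_shape shape `c(rows, cols)` of the scene the insert is for.
#' @param rng_seed seed for the placement offset.
#' @return A list of class `rasp_aggregate`: `roi`, `otsu_mask`,
#'   `distance_map`, `scaling_factor`, `corrected`, `offset` (0-based
#'   `c(row, col)` padding offset), `padded_image` and `padded_mask`.
#' @export
prepare_aggregate <- function(roi, a = 10, target_shape, rng_seed = NULL) {
  check_image(roi, arg = "roi")
  if (a <= 0) stop_validation("`a` must be positive")
  target_shape <- as.integer(target_shape)
  if (any(dim(roi) > target_shape))
    stop_validation("`roi` is larger than `target_shape`")
  rng <- range(roi)
  if (rng[1] == rng[2]) stop_validation("`roi` is constant: empty Otsu foreground")
  thr <- rng[1] + diff(rng) * EBImage::otsu((roi - rng[1]) / diff(rng))
  mask <- roi > thr
  if (!any(mask)) stop_validation("empty Otsu foreground in `roi`")
  d <- as.matrix(EBImage::distmap(1 - mask, metric = "euclidean"))
  corr <- 2 / (1 + exp(d / a))
  corrected <- roi * corr
  off <- with_seed(rng_seed, c(
    sample.int(target_shape[1] - nrow(roi) + 1L, 1L) - 1L,
    sample.int(target_shape[2] - ncol(roi) + 1L, 1L) - 1L))
  padded <- matrix(0, target_shape[1], target_shape[2])
  padded[off[1] + seq_len(nrow(roi)), off[2] + seq_len(ncol(roi))] <- corrected
  pmask <- matrix(FALSE, target_shape[1], target_shape[2])
  pmask[off[1] + seq_len(nrow(roi)), off[2] + seq_len(ncol(roi))] <- mask
  structure(list(roi = roi, otsu_mask = mask, distance_map = d,
                 scaling_factor = a, corrected = corrected, offset = off,
                 padded_image = padded, padded_mask = pmask),
            class = "rasp_aggregate")
}

#' Generate a synthetic large-aggregate ROI
#'
#' Programmatic stand-in for a manually cropped aggregate library: a smooth
#' random field is thresholded into an irregular blob and given mild
#' multiplicative texture. Any user-supplied ROI (e.g. read from TIFF) can be
#' used with [prepare_aggregate()] instead.
#'
#' @param shape ROI shape (default 80x80).
#' @param amplitude approximate peak intensity of the aggregate (photons).
#' @param rng_seed seed.
#' @param texture multiplicative texture strength (0 disables).
#' @param baseline additive floor emulating residual structured background in
#'   the crop (photons).
#' @return Numeric matrix.
#' @export
random_aggregate_roi <- function(shape = c(80L, 80L), amplitude = 500,
                                 rng_seed = NULL, texture = 0.2,
                                 baseline = 20) {
  shape <- as.integer(shape)
  with_seed(rng_seed, {
    z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    s <- convolve2(z, gaussian_kernel(min(shape) / 10))
    s <- (s - min(s)) / (max(s) - min(s))
    q <- rasp_quantile(s, 0.75)
    blob <- pmax(s - q, 0) / (1 - q)
    # Texture is band-limited at 3 px, broader than the point-spread
    # function: pixel-independent modulation cannot arise optically, and
    # bumps at exactly the PSF scale would be genuine unlabeled puncta,
    # corrupting the ground-truth bookkeeping.
    tz <- convolve2(matrix(stats::rnorm(prod(shape)), shape[1], shape[2]),
                    gaussian_kernel(3))
    tex <- 1 + texture * tz / stats::sd(tz)
    pmax(amplitude * blob * tex, 0) + baseline * s
  })
}

#' Compose a synthetic scene
#'
#' Sums the background, the Poisson-noised punctum image and the aggregate
#' inserts pixel-wise, and finalizes the ground-truth table: any punctum
#' whose mask intersects an aggregate footprint is deleted from the truth
#' table (its photons remain in the image); for each surviving punctum the
#' true background is the mean background over its mask, and the true
#' contrast-to-noise ratio is the background-subtracted signal maximum over
#' the mask divided by the standard deviation of the background there
#' (sample sd; `NA` if the background is locally constant).
#'
#' @param background background image (photons).
#' @param puncta a `rasp_puncta` whose `image` has had Poisson noise applied
#'   (see [add_poisson_noise()]); if present, element `noiseless` is used for
#'   the truth bookkeeping instead of the noisy image.
#' @param aggregates list of [prepare_aggregate()] inserts (may be empty).
#' @param rng_seed recorded in the scene for provenance.
#' @return A list of class `rasp_scene`: `image`, `background`,
#'   `puncta_image`, `aggregates_image`, `truth` (with `background_true`,
#'   `sigma_b_true`, `cnr_true` added), `masks`, `n_deleted`, `rng_seed`.
#'   The components satisfy
#'   `image == background + puncta_image + aggregates_image` exactly.
#' @export
compose_scene <- function(background, puncta, aggregates = list(),
                          rng_seed = NULL) {
  check_image(background, arg = "background")
  if (!is.list(puncta) || is.null(puncta$image) || is.null(puncta$truth))
    stop_validation("`puncta` must carry `image` and `truth` (see render_puncta_grid)")
  if (!identical(dim(background), dim(puncta$image)))
    stop_validation("component shapes differ")
  agg_img <- matrix(0, nrow(background), ncol(background))
  agg_mask <- matrix(FALSE, nrow(background), ncol(background))
  for (ag in aggregates) {
    if (!inherits(ag, "rasp_aggregate"))
      stop_validation("`aggregates` must be prepare_aggregate() results")
    if (!identical(dim(ag$padded_image), dim(background)))
      stop_validation("component shapes differ")
    agg_img <- agg_img + ag$padded_image
    agg_mask <- agg_mask | ag$padded_mask
  }
  spot_img <- puncta$noiseless %||% puncta$image
  truth <- puncta$truth
  masks <- puncta$masks
  overlap <- vapply(masks, function(ix) length(ix) > 0L && any(agg_mask[ix]),
                    logical(1))
  n_deleted <- sum(overlap)
  truth <- truth[!overlap, , drop = FALSE]
  masks <- masks[!overlap]
  bg_true <- vapply(masks, function(ix) mean(background[ix]), numeric(1))
  sigma_b <- vapply(masks, function(ix)
    if (length(ix) > 1L) stats::sd(background[ix]) else NA_real_, numeric(1))
  s_a <- vapply(masks, function(ix) max(background[ix] + spot_img[ix]), numeric(1))
  truth$background_true <- bg_true
  truth$sigma_b_true <- sigma_b
  truth$cnr_true <- ifelse(is.na(sigma_b) | sigma_b == 0, NA_real_,
                           (s_a - bg_true) / sigma_b)
  structure(list(image = background + puncta$image + agg_img,
                 background = background, puncta_image = puncta$image,
                 aggregates_image = agg_img, truth = truth, masks = masks,
                 n_deleted = n_deleted, rng_seed = rng_seed),
            class = "rasp_scene")
}

#' @export
print.rasp_scene <- function(x, ...) {
  cat(sprintf("rasp scene: %dx%d px, %d truth puncta (%d deleted under aggregates)\n",
              nrow(x$image), ncol(x$image), nrow(x$truth), x$n_deleted))
  if (nrow(x$truth) > 0)
    cat(sprintf("  mean true CNR %.2f, mean true background %.1f photons\n",
                mean(x$truth$cnr_true, na.rm = TRUE),
                mean(x$truth$background_true)))
  invisible(x)
}

#' Synthetic structured background
#'
#' Emulates the background components of real tissue images: a spatially
#' structured autofluorescence level
#' `L = mean_level * (1 + structure_contrast * S)` — `S` a unit-variance
#' Gaussian random field smoothed at `structure_sigma` — sampled through
#' Poisson shot noise, plus Gaussian detector read noise, clipped at zero:
#' `background = max(0, Poisson(max(L, 0)) + N(0, read_noise_sd))`.
#' Shot noise on the autofluorescence is essential: it makes the pixel noise
#' scale as the square root of the local level, as photon counting demands;
#' a level-independent noise floor would plant unphysically sharp features
#' in dim regions. The generator is a stand-in for real negative-control
#' images, which are not shipped with the package.
#'
#' @param shape image shape `c(rows, cols)`.
#' @param mean_level mean background level (photons).
#' @param read_noise_sd Gaussian detector read-noise sd (photons).
#' @param structure_sigma correlation scale of the structure (px).
#' @param structure_contrast relative contrast of the structure.
#' @param rng_seed seed.
#' @return Numeric matrix.
#' @export
synth_background <- function(shape, mean_level = 100, read_noise_sd = 3,
                             structure_sigma = 8, structure_contrast = 0.4,
                             rng_seed = NULL) {
  shape <- as.integer(shape)
  if (mean_level <= 0 || read_noise_sd < 0 || structure_sigma <= 0 ||
      structure_contrast < 0)
    stop_validation("background parameters must be positive (noise/contrast >= 0)")
  with_seed(rng_seed, {
    n <- prod(shape)
    level <- matrix(mean_level, shape[1], shape[2])
    if (structure_contrast > 0) {
      z <- matrix(stats::rnorm(n), shape[1], shape[2])
      s <- convolve2(z, gaussian_kernel(structure_sigma))
      s <- (s - mean(s)) / stats::sd(s)
      level <- mean_level * (1 + structure_contrast * s)
    }
    img <- matrix(stats::rpois(n, pmax(level, 0)), shape[1], shape[2])
    if (read_noise_sd > 0)
      img <- img + matrix(stats::rnorm(n, sd = read_noise_sd), shape[1], shape[2])
    pmax(img, 0)
  })
}

#' Scene series at controlled contrast-to-noise ratios
#'
#' Generates one scene per requested CNR with identical punctum positions,
#' background and aggregates across the series; only the punctum amplitude
#' changes (and the Poisson noise realization, per scene). The amplitude for
#' each scene is solved by bisection on the noiseless render so that the mean
#' realized `cnr_true` over the surviving puncta matches the request within
#' 5% (an error is raised if it cannot).
#'
#' @param shape image shape `c(rows, cols)`.
#' @param cnr_values vector of positive target CNRs (the published validation
#'   sweeps 2 to 12).
#' @param n_puncta puncta per scene (400 emulates the widefield validation
#'   density on a 1200x1200 field, 1600 the confocal one).
#' @param sigma punctum width (px).
#' @param arrangement passed to [render_puncta_grid()].
#' @param background optional background matrix; by default one is generated
#'   with [synth_background()] using `background_args`.
#' @param background_args list of overrides for [synth_background()].
#' @param n_aggregates number of synthetic large aggregates (default 0).
#' @param aggregate_amplitude,aggregate_shape passed to
#'   [random_aggregate_roi()].
#' @param rng_seed master seed; all internal seeds derive from it.
#' @return List of `rasp_scene` objects, one per CNR.
#' @export
scene_series_by_cnr <- function(shape, cnr_values, n_puncta = 400,
                                sigma = 1.4, arrangement = "uniform_random",
                                background = NULL, background_args = list(),
                                n_aggregates = 0L, aggregate_amplitude = 500,
                                aggregate_shape = c(80L, 80L), rng_seed = 1L) {
  if (any(cnr_values <= 0)) stop_validation("`cnr_values` must be positive")
  shape <- as.integer(shape)
  if (is.null(background)) {
    background <- do.call(synth_background,
                          c(list(shape = shape, rng_seed = derive_seed(rng_seed, 2)),
                            background_args))
  }
  if (!identical(dim(background), shape))
    stop_validation("`background` shape differs from `shape`")
  aggregates <- lapply(seq_len(n_aggregates), function(i) {
    roi <- random_aggregate_roi(aggregate_shape, aggregate_amplitude,
                                rng_seed = derive_seed(rng_seed, 100 + i))
    prepare_aggregate(roi, a = 10, target_shape = shape,
                      rng_seed = derive_seed(rng_seed, 200 + i))
  })
  agg_mask <- Reduce(`|`, lapply(aggregates, `[[`, "padded_mask"),
                     matrix(FALSE, shape[1], shape[2]))

  unit <- render_puncta_grid(shape, n_puncta, amplitude = 1, sigma = sigma,
                             arrangement = arrangement,
                             rng_seed = derive_seed(rng_seed, 1))
  survives <- !vapply(unit$masks, function(ix) length(ix) > 0L && any(agg_mask[ix]),
                      logical(1))
  if (!any(survives))
    stop_validation("all puncta fall under aggregates; nothing to calibrate on")
  keep <- which(survives)
  bg_mean <- vapply(unit$masks[keep], function(ix) mean(background[ix]), numeric(1))
  bg_sd <- vapply(unit$masks[keep], function(ix) stats::sd(background[ix]), numeric(1))
  # Puncta sitting on locally constant background (e.g. zero-clipped dead
  # zones) have no defined CNR; they stay in the truth table with
  # cnr_true = NA but are excluded from the amplitude calibration.
  measurable <- is.finite(bg_sd) & bg_sd > 0
  if (!any(measurable))
    stop_validation(paste(
      "unattainable CNR: background is locally constant under every punctum;",
      "attainable only with a noisy/structured background"))
  keep <- keep[measurable]
  bg_mean <- bg_mean[measurable]
  bg_sd <- bg_sd[measurable]
  unit_vals <- lapply(keep, function(i) unit$image[unit$masks[[i]]])
  bg_vals <- lapply(keep, function(i) background[unit$masks[[i]]])
  realized <- function(amp) {
    mean(mapply(function(u, b, m, s) (max(b + amp * u) - m) / s,
                unit_vals, bg_vals, bg_mean, bg_sd))
  }
  scenes <- vector("list", length(cnr_values))
  for (j in seq_along(cnr_values)) {
    target <- cnr_values[j]
    lo <- 0
    hi <- 1
    expand <- 0L
    while (realized(hi) < target && expand < 60L) {
      hi <- hi * 2
      expand <- expand + 1L
    }
    if (realized(hi) < target)
      stop_validation(sprintf(
        "requested CNR %.3g not realizable; attainable range roughly (0, %.3g]",
        target, realized(hi)))
    if (realized(lo + 1e-12) > target)
      stop_validation(sprintf(
        "requested CNR %.3g below the background floor %.3g of this scene",
        target, realized(1e-12)))
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      r <- realized(mid)
      if (abs(r - target) / target < 0.005) break
      if (r < target) lo <- mid else hi <- mid
    }
    amp <- mid
    r <- realized(amp)
    if (abs(r - target) / target > 0.05)
      stop_validation(sprintf(
        "requested CNR %.3g not realizable (got %.3g)", target, r))
    noiseless <- amp * unit$image
    noisy <- add_poisson_noise(noiseless, rng_seed = derive_seed(rng_seed, 1000 + j))
    truth <- unit$truth
    truth$amplitude <- amp
    truth$peak_true <- amp * truth$peak_true
    truth$sum_intensity_true <- amp * truth$sum_intensity_true
    scenes[[j]] <- compose_scene(
      background,
      list(image = noisy, noiseless = noiseless, truth = truth,
           masks = unit$masks),
      aggregates, rng_seed = rng_seed)
  }
  scenes
}
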