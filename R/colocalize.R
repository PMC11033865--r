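#' Inside-cell ratio (ICR)
#'
#' Fraction of puncta whose (rounded) position falls on a nonzero pixel of
#' the binary cell mask. A punctum landing exactly on a mask boundary pixel
#' counts as inside (pixel-membership rule).
#'
#' @param puncta_positions `n x 2` `(row, col)` matrix or data frame
#'   (fractional positions are rounded to the containing pixel).
#' @param mask binary matrix (nonzero = cell).
#' @return Fraction in `[0, 1]`.
#' @section Errors: an empty position list raises an error of class
#'   `rasp_empty_fov` (the field of view is skipped and logged upstream).
#' @export
inside_cell_ratio <- function(puncta_positions, mask) {
  check_image(mask * 1, arg = "mask")
  pos <- as_positions(puncta_positions)
  if (nrow(pos) == 0L)
    stop_rasp("ICR undefined: no puncta in this field of view",
              c("rasp_empty_fov", "rasp_validation_error"))
  r <- round(pos[, 1]); c <- round(pos[, 2])
  if (any(r < 1 | r > nrow(mask) | c < 1 | c > ncol(mask)))
    stop_validation("punctum positions outside the image")
  mean(mask[cbind(r, c)] > 0)
}

#' Colocalization likelihood
#'
#' Ratio of the inside-cell ratio to the cell-mask area fraction — the ICR
#' that uniformly random puncta would give in expectation. Values above 1
#' mean enrichment of puncta inside cells, below 1 depletion.
#'
#' @param icr inside-cell ratio.
#' @param mask_fraction fraction of image pixels inside cells (> 0).
#' @return Dimensionless likelihood.
#' @export
colocalization_likelihood <- function(icr, mask_fraction) {
  if (any(mask_fraction <= 0)) stop_validation("`mask_fraction` must be positive")
  icr / mask_fraction
}

#' Complete-spatial-randomness (CSR) reference
#'
#' Draws `n_puncta` positions uniformly over all image pixels, `n_repeats`
#' times, and computes the colocalization likelihood of each draw. With
#' enough positions these likelihoods converge to 1; their sample standard
#' deviation serves as the error bound on a measured likelihood for this
#' field of view.
#'
#' @param mask binary cell mask.
#' @param n_puncta positions per draw (matched to the real punctum count).
#' @param n_repeats number of CSR draws (>= 2).
#' @param rng_seed seed.
#' @return `list(likelihoods =, error_bound =)` with `error_bound` the
#'   sample sd over repeats.
#' @export
csr_reference <- function(mask, n_puncta, n_repeats = 100, rng_seed = NULL) {
  check_image(mask * 1, arg = "mask")
  if (n_puncta < 1) stop_validation("`n_puncta` must be >= 1")
  if (n_repeats < 2) stop_validation("`n_repeats` must be >= 2")
  mf <- mean(mask > 0)
  if (mf <= 0 || mf >= 1)
    stop_validation("`mask` must cover a nonzero, non-total fraction of the image")
  nr <- nrow(mask); nc <- ncol(mask)
  lik <- with_seed(rng_seed, vapply(seq_len(n_repeats), function(i) {
    r <- sample.int(nr, n_puncta, replace = TRUE)
    c <- sample.int(nc, n_puncta, replace = TRUE)
    mean(mask[cbind(r, c)] > 0) / mf
  }, numeric(1)))
  list(likelihoods = lik, error_bound = stats::sd(lik))
}

#' Colocalization statistics for one field of view
#'
#' Bundles the per-FOV quantities: mask fraction, punctum counts, ICR,
#' colocalization likelihood, and the CSR error bound.
#'
#' @param puncta_positions `n x 2` `(row, col)` positions (or a
#'   `rasp_detections` frame; accepted candidates are used).
#' @param mask binary cell mask.
#' @param n_repeats CSR repeats for the error bound.
#' @param rng_seed seed.
#' @param fov_id identifier recorded in the result.
#' @return A list of class `rasp_coloc` with fields `fov_id`,
#'   `mask_fraction`, `n_puncta`, `n_inside`, `icr`, `likelihood`,
#'   `csr_likelihoods`, `csr_error_bound`.
#' @export
colocalize_fov <- function(puncta_positions, mask, n_repeats = 100,
                           rng_seed = NULL, fov_id = NA_character_) {
  pos <- as_positions(puncta_positions)
  icr <- inside_cell_ratio(pos, mask)
  mf <- mean(mask > 0)
  csr <- csr_reference(mask, nrow(pos), n_repeats, rng_seed)
  structure(list(fov_id = fov_id, mask_fraction = mf, n_puncta = nrow(pos),
                 n_inside = as.integer(round(icr * nrow(pos))), icr = icr,
                 likelihood = colocalization_likelihood(icr, mf),
                 csr_likelihoods = csr$likelihoods,
                 csr_error_bound = csr$error_bound),
            class = "rasp_coloc")
}

#' @export
print.rasp_coloc <- function(x, ...) {
  cat(sprintf("FOV %s: %d puncta, ICR %.3f, mask fraction %.3f, likelihood %.3f +- %.3f (CSR)\n",
              x$fov_id, x$n_puncta, x$icr, x$mask_fraction, x$likelihood,
              x$csr_error_bound))
  invisible(x)
}

#' Aggregate colocalization results over fields of view
#'
#' Mean and sample sd of the per-FOV colocalization likelihoods and of the
#' per-FOV CSR error bounds, plus a histogram of the likelihoods. Skipped
#' FOVs (passed as `NULL`, e.g. empty masks or zero detections) are counted,
#' not imputed. With a single valid FOV the sd is reported as 0 and flagged.
#'
#' @param per_fov list of `rasp_coloc` results (`NULL` entries = skipped).
#' @return A list of class `rasp_coloc_summary`: `n_fov`, `n_skipped`,
#'   `mean_likelihood`, `sd_likelihood`, `mean_error_bound`,
#'   `sd_error_bound`, `single_fov` flag, and `histogram`
#'   (`list(breaks, counts)`).
#' @export
aggregate_fovs <- function(per_fov) {
  valid <- Filter(function(x) inherits(x, "rasp_coloc"), per_fov)
  n_skipped <- length(per_fov) - length(valid)
  if (length(valid) < 1L) stop_validation("no valid fields of view")
  lik <- vapply(valid, `[[`, numeric(1), "likelihood")
  eb <- vapply(valid, `[[`, numeric(1), "csr_error_bound")
  single <- length(lik) == 1L
  h <- graphics::hist(lik, plot = FALSE)
  structure(list(n_fov = length(valid), n_skipped = n_skipped,
                 mean_likelihood = mean(lik),
                 sd_likelihood = if (single) 0 else stats::sd(lik),
                 mean_error_bound = mean(eb),
                 sd_error_bound = if (single) 0 else stats::sd(eb),
                 single_fov = single,
                 histogram = list(breaks = h$breaks, counts = h$counts)),
            class = "rasp_coloc_summary")
}

#' @export
print.rasp_coloc_summary <- function(x, ...) {
  cat(sprintf("colocalization over %d FOV(s) (%d skipped): likelihood %.3f +- %.3f; CSR error bound %.3f +- %.3f\n",
              x$n_fov, x$n_skipped, x$mean_likelihood, x$sd_likelihood,
              x$mean_error_bound, x$sd_error_bound))
  if (x$single_fov) cat("  (single FOV: sd reported as 0)\n")
  invisible(x)
}
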