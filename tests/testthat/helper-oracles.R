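# Naive double-loop reference implementations used as independent oracles
# for the radiality kernels, plus small fixture builders. Deliberately slow
# and literal.

# Chebyshev ring pixels by scanning the whole window.
ref_ring <- function(center, r) {
  px <- NULL
  for (dr in -r:r) for (dc in -r:r) {
    if (max(abs(dr), abs(dc)) == r)
      px <- rbind(px, c(center[1] + dr, center[2] + dc))
  }
  px
}

ref_flatness <- function(image, center, r = 2) {
  px <- ref_ring(center, r)
  total <- 0
  for (i in seq_len(nrow(px))) total <- total + image[px[i, 1], px[i, 2]]
  (total / nrow(px)) / image[center[1], center[2]]
}

# Central differences inside, one-sided at borders, evaluated pointwise.
ref_gradient_at <- function(image, rr, cc) {
  nr <- nrow(image); nc <- ncol(image)
  gx <- if (cc == 1) image[rr, 2] - image[rr, 1]
        else if (cc == nc) image[rr, nc] - image[rr, nc - 1]
        else (image[rr, cc + 1] - image[rr, cc - 1]) / 2
  gy <- if (rr == 1) image[2, cc] - image[1, cc]
        else if (rr == nr) image[nr, cc] - image[nr - 1, cc]
        else (image[rr + 1, cc] - image[rr - 1, cc]) / 2
  sqrt(gx^2 + gy^2)
}

ref_integrated_gradient <- function(image, center, r = 2) {
  px <- ref_ring(center, r)
  total <- 0
  for (i in seq_len(nrow(px)))
    total <- total + ref_gradient_at(image, px[i, 1], px[i, 2])
  total
}

# Isotropic 2D Gaussian sampled at pixel centers; sigma_x/sigma_y allow the
# elongated (asymmetric) control.
gauss_patch <- function(shape, center, A, sigma, sigma_y = sigma) {
  rows <- seq_len(shape[1]); cols <- seq_len(shape[2])
  A * exp(-outer((rows - center[1])^2 / (2 * sigma_y^2),
                 (cols - center[2])^2 / (2 * sigma^2), "+"))
}

random_patch <- function(n = 11, lambda = 50) {
  matrix(rpois(n * n, lambda), n, n)
}
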