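test_that("enhancement annihilates constants and affine ramps, peaks on puncta", {
  cfg <- detection_config()
  expect_equal(enhance(matrix(5, 32, 32), cfg), matrix(0, 32, 32),
               tolerance = 1e-10)

  ramp <- outer(rep(1, 40), 1:40) * 3 + 7
  enh <- enhance(ramp, cfg)
  expect_lt(max(abs(enh[15:26, 15:26])), 1e-8)

  # single punctum on zero background: global enhanced maximum within 1 px
  img <- gauss_patch(c(41, 41), c(21, 25), 500, 1.4)
  enh <- enhance(img, cfg)
  pk <- which(enh == max(enh), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(pk - c(21, 25))), 1)

  expect_error(enhance(matrix(c(1, NA, 3, 4), 2, 2)), class = "rasp_validation_error")
})

test_that("threshold mask keeps the top percentile with ties", {
  m <- matrix(sample(1:100), 10, 10)
  mask <- threshold_mask(m, 5)
  expect_identical(sort(m[mask]), 96:100)

  m10 <- matrix(sample(1:10), 2, 5)
  expect_identical(sort(m10[threshold_mask(m10, 50)]), 6:10)

  expect_warning(out <- threshold_mask(matrix(1, 4, 4), 5), "degenerate")
  expect_true(all(out))

  # monotone: raising the kept percentage never drops a selected pixel
  set.seed(7)
  e <- matrix(rnorm(400), 20, 20)
  m5 <- threshold_mask(e, 5)
  m20 <- threshold_mask(e, 20)
  expect_true(all(m20[m5]))
})

test_that("candidate extraction labels 8-connected objects and measures them", {
  img <- matrix(10, 30, 30)
  mask <- matrix(FALSE, 30, 30)
  mask[5:7, 5:7] <- TRUE
  mask[20:22, 20:22] <- TRUE
  img[6, 6] <- 50; img[21, 21] <- 80
  det <- extract_candidates(img, mask)
  expect_equal(nrow(det), 2)
  expect_equal(det$area, c(9L, 9L))
  expect_equal(det$peak_row, c(6L, 21L))

  # diagonally touching blocks form one 8-connected object
  mask2 <- matrix(FALSE, 20, 20)
  mask2[5:6, 5:6] <- TRUE; mask2[7:8, 7:8] <- TRUE
  expect_equal(nrow(extract_candidates(img[1:20, 1:20], mask2)), 1)

  # peak at the border: ring leaves the image, candidate dropped and counted
  mask3 <- matrix(FALSE, 20, 20)
  mask3[1:2, 9:11] <- TRUE
  img3 <- matrix(10, 20, 20); img3[1, 10] <- 99
  det3 <- extract_candidates(img3, mask3)
  expect_equal(nrow(det3), 0)
  expect_equal(attr(det3, "n_edge_dropped"), 1L)

  expect_equal(nrow(extract_candidates(img, matrix(FALSE, 30, 30))), 0)
})

test_that("peak ties break to the lexicographically lowest pixel", {
  img <- matrix(0, 15, 15)
  mask <- matrix(FALSE, 15, 15)
  mask[7:9, 7:9] <- TRUE
  img[mask] <- 5  # all tied
  det <- extract_candidates(img, mask)
  expect_equal(c(det$peak_row, det$peak_col), c(7L, 7L))
})

test_that("per-candidate metrics equal the scalar kernels on the raw image", {
  set.seed(11)
  img <- matrix(rpois(64 * 64, 30), 64, 64)
  det <- detect_puncta(img)
  expect_gt(nrow(det), 0)
  for (i in seq_len(min(nrow(det), 20))) {
    ring <- ring_coordinates(c(det$peak_row[i], det$peak_col[i]), 2, dim(img))
    expect_equal(det$flatness[i], flatness(img, ring), tolerance = 1e-12)
    expect_equal(det$integrated_gradient[i],
                 integrated_gradient(gradient_field(img), ring),
                 tolerance = 1e-12)
  }
})

test_that("intensity and background estimation recovers constructed values", {
  b <- 20
  img <- matrix(b, 41, 41) + gauss_patch(c(41, 41), c(21, 21), 300, 1.4)
  mask <- img > b + 300 * 0.1
  pix <- which(mask)
  # annulus pushed to Chebyshev 5..8 where the Gaussian tail is < 0.2%
  est <- estimate_intensity_background(img, pix, c(21, 21), annulus = c(5, 8))
  spot_sum <- sum(gauss_patch(c(41, 41), c(21, 21), 300, 1.4)[pix])
  expect_equal(est$local_background, b, tolerance = 5e-3)
  expect_equal(est$sum_intensity, spot_sum, tolerance = 0.01)

  zero <- matrix(0, 20, 20)
  est0 <- estimate_intensity_background(zero, which(zero > -1)[1:4], c(10, 10))
  expect_equal(est0$sum_intensity, 0)
  expect_equal(est0$local_background, 0)

  expect_error(estimate_intensity_background(img, pix, c(21, 21), annulus = c(5, 3)),
               class = "rasp_validation_error")
})

test_that("background-only sum intensities average to zero within noise", {
  set.seed(23)
  vals <- replicate(50, {
    img <- matrix(rpois(31 * 31, 100), 31, 31)
    est <- estimate_intensity_background(img, c(16 + 31 * 15, 17 + 31 * 15,
                                                16 + 31 * 16), c(16, 16))
    est$sum_intensity
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 1)
})

test_that("detection finds well-separated puncta and is translation-equivariant", {
  p <- render_puncta_grid(c(200, 200), 25, amplitude = 400, sigma = 1.4,
                          arrangement = "grid")
  img <- p$image + 10
  det <- detect_puncta(img)
  expect_gte(nrow(det), 25)
  m <- match_detections(cbind(p$truth$y0, p$truth$x0), det, 2)
  expect_equal(m$tp, 25)

  # integer shift moves all interior peaks by the same vector
  sh <- 7
  img2 <- matrix(10, 200, 200)
  img2[(sh + 1):200, (sh + 1):200] <- img[1:(200 - sh), 1:(200 - sh)]
  det2 <- detect_puncta(img2)
  k1 <- det[order(det$peak_row, det$peak_col), ]
  k1 <- k1[k1$peak_row < 180 & k1$peak_col < 180 &
             img[cbind(k1$peak_row, k1$peak_col)] > 100, ]
  k2 <- det2[order(det2$peak_row, det2$peak_col), ]
  k2 <- k2[k2$peak_row > sh + 5 & k2$peak_col > sh + 5, ]
  shifted <- cbind(k1$peak_row + sh, k1$peak_col + sh)
  expect_true(all(apply(shifted, 1, function(pp)
    min((k2$peak_row - pp[1])^2 + (k2$peak_col - pp[2])^2) == 0)))

  expect_equal(nrow(suppressWarnings(detect_puncta(matrix(0, 64, 64)))), 0)
})

test_that("boundary filtering never adds candidates and flags rejects", {
  set.seed(31)
  img <- synth_background(c(128, 128), rng_seed = 5)
  det <- detect_puncta(img)
  b <- structure(list(flatness_cutoff = median(det$flatness),
                      ig_cutoff = median(det$integrated_gradient),
                      percentile = 5, mode = "and",
                      n_training_candidates = nrow(det),
                      provenance = "synthetic"),
                 class = "rasp_boundary")
  detf <- apply_boundary(det, b)
  expect_equal(nrow(detf), nrow(det))
  expect_lte(sum(detf$passed_filter), sum(det$passed_filter))
  rejected <- detf[!detf$passed_filter, ]
  expect_true(all(rejected$flatness > b$flatness_cutoff |
                  rejected$integrated_gradient < b$ig_cutoff))
})
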