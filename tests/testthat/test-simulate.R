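test_that("rendered puncta integrate to the analytic Gaussian mass", {
  p <- render_puncta_grid(c(201, 201), 1, amplitude = 1000, sigma = 1.4,
                          arrangement = "grid")
  expect_equal(sum(p$image), 2 * pi * 1.4^2 * 1000, tolerance = 1e-3)
  expect_equal(max(p$image), 1000, tolerance = 0.3)  # grid center subpixel
  expect_gt(length(p$masks[[1]]), 0)
  expect_equal(p$truth$sum_intensity_true, sum(p$image[p$masks[[1]]]))

  p0 <- render_puncta_grid(c(64, 64), 4, amplitude = 0, arrangement = "grid")
  expect_equal(p0$image, matrix(0, 64, 64))
  expect_true(all(lengths(p0$masks) == 0))
})

test_that("puncta keep a 6-sigma separation in both arrangements", {
  for (arr in c("grid", "uniform_random")) {
    p <- render_puncta_grid(c(400, 400), 36, amplitude = 100, sigma = 1.4,
                            arrangement = arr, rng_seed = 5)
    d <- as.matrix(dist(cbind(p$truth$x0, p$truth$y0)))
    diag(d) <- Inf
    expect_gte(min(d), 6 * 1.4)
  }
  expect_error(render_puncta_grid(c(50, 50), 100, amplitude = 10,
                                  arrangement = "grid"),
               class = "rasp_validation_error")
  # grid positions are seed-independent
  a <- render_puncta_grid(c(200, 200), 9, 10, arrangement = "grid", rng_seed = 1)
  b <- render_puncta_grid(c(200, 200), 9, 10, arrangement = "grid", rng_seed = 99)
  expect_equal(a$truth$x0, b$truth$x0)
})

test_that("Poisson stage is seeded, integer, and mean-variance matched", {
  expect_equal(add_poisson_noise(matrix(0, 10, 10)), matrix(0L, 10, 10))
  expect_error(add_poisson_noise(matrix(-1, 2, 2)), class = "rasp_validation_error")

  x1 <- add_poisson_noise(matrix(50, 50, 50), rng_seed = 9)
  x2 <- add_poisson_noise(matrix(50, 50, 50), rng_seed = 9)
  expect_identical(x1, x2)
  expect_true(all(x1 == round(x1)))

  x <- add_poisson_noise(matrix(100, 1000, 1000), rng_seed = 2)
  expect_lt(abs(mean(x) - 100), 3 * sqrt(100 / 1e6))
  expect_gt(var(as.numeric(x)) / mean(x), 0.99)
  expect_lt(var(as.numeric(x)) / mean(x), 1.01)
})

test_that("aggregate preparation follows the distance-transform sigmoid", {
  set.seed(5)
  # all-foreground ROI: distance 0 everywhere -> corrected equals ROI
  roi_bin <- matrix(c(rep(100, 30), rep(0, 6)), 6, 6)
  agg <- prepare_aggregate(roi_bin, a = 10, target_shape = c(30, 30), rng_seed = 1)
  expect_equal(agg$corrected[agg$otsu_mask], roi_bin[agg$otsu_mask])
  expect_true(all(agg$distance_map[agg$otsu_mask] == 0))

  # 1-Lipschitz distance map (neighbors differ by at most sqrt(2))
  roi <- random_aggregate_roi(c(40, 40), 300, rng_seed = 3)
  agg2 <- prepare_aggregate(roi, a = 10, target_shape = c(80, 80), rng_seed = 2)
  d <- agg2$distance_map
  expect_lte(max(abs(diff(d))), sqrt(2) + 1e-9)
  expect_lte(max(abs(t(diff(t(d))))), sqrt(2) + 1e-9)

  # sigmoid decay: c(d = 10 a) < 1e-3, so corrected is ~0 there
  far <- d >= 100
  if (any(far)) expect_lt(max(agg2$corrected[far] / max(roi)), 1e-3)
  expect_equal(2 / (1 + exp(10)), 9.08e-5, tolerance = 1e-3)

  # seeded placement is reproducible
  agg3 <- prepare_aggregate(roi, a = 10, target_shape = c(80, 80), rng_seed = 2)
  expect_identical(agg2$offset, agg3$offset)

  expect_error(prepare_aggregate(matrix(5, 4, 4), 10, c(10, 10)),
               class = "rasp_validation_error")
})

test_that("scene composition is exactly additive and prunes covered puncta", {
  p <- render_puncta_grid(c(120, 120), 9, amplitude = 200, sigma = 1.4,
                          arrangement = "grid")
  noisy <- add_poisson_noise(p$image, rng_seed = 4)
  bg <- synth_background(c(120, 120), rng_seed = 6)
  sc <- compose_scene(bg, list(image = noisy, noiseless = p$image,
                               truth = p$truth, masks = p$masks))
  expect_identical(sc$image, sc$background + sc$puncta_image + sc$aggregates_image)
  expect_equal(nrow(sc$truth), 9)

  # an aggregate placed over known puncta deletes them from the truth table
  # but not from the image
  roi <- matrix(500, 40, 40) + matrix(runif(1600), 40, 40)
  agg <- prepare_aggregate(roi, a = 10, target_shape = c(120, 120), rng_seed = 8)
  covered <- vapply(p$masks, function(ix) any(agg$padded_mask[ix]), logical(1))
  expect_gt(sum(covered), 0)
  sc2 <- compose_scene(bg, list(image = noisy, noiseless = p$image,
                                truth = p$truth, masks = p$masks), list(agg))
  expect_equal(nrow(sc2$truth), 9 - sum(covered))
  expect_equal(sc2$n_deleted, sum(covered))
  expect_identical(sc2$image, sc2$background + sc2$puncta_image + sc2$aggregates_image)

  expect_error(compose_scene(bg[1:50, ], list(image = noisy, truth = p$truth,
                                              masks = p$masks)),
               class = "rasp_validation_error")
})

test_that("per-punctum truth bookkeeping matches direct arithmetic", {
  p <- render_puncta_grid(c(100, 100), 4, amplitude = 300, sigma = 1.4,
                          arrangement = "grid")
  bg <- synth_background(c(100, 100), rng_seed = 14)
  sc <- compose_scene(bg, list(image = p$image, noiseless = p$image,
                               truth = p$truth, masks = p$masks))
  for (i in 1:4) {
    ix <- sc$masks[[i]]
    expect_equal(sc$truth$background_true[i], mean(bg[ix]))
    expect_equal(sc$truth$cnr_true[i],
                 (max(bg[ix] + p$image[ix]) - mean(bg[ix])) / sd(bg[ix]))
  }
})

test_that("synthetic background is seeded and structured as configured", {
  flat <- synth_background(c(64, 64), mean_level = 80, read_noise_sd = 0,
                           structure_sigma = 5, structure_contrast = 0,
                           rng_seed = 3)
  # contrast 0 leaves only shot noise around the mean level
  expect_equal(mean(flat), 80, tolerance = 0.01)
  expect_equal(sd(flat), sqrt(80), tolerance = 0.1)

  b1 <- synth_background(c(64, 64), rng_seed = 17)
  expect_identical(b1, synth_background(c(64, 64), rng_seed = 17))

  # autocorrelation length grows with structure_sigma
  acl <- vapply(c(2, 8), function(s) {
    b <- synth_background(c(256, 256), structure_sigma = s,
                          structure_contrast = 0.5, read_noise_sd = 0,
                          rng_seed = 19)
    z <- b - mean(b)
    lag <- 4
    sum(z[, 1:(256 - lag)] * z[, (lag + 1):256]) / sum(z^2)
  }, numeric(1))
  expect_gt(acl[2], acl[1])
})

test_that("CNR series hits requested contrasts at fixed positions", {
  scenes <- scene_series_by_cnr(c(256, 256), c(4, 8.7), n_puncta = 16,
                                rng_seed = 21)
  expect_length(scenes, 2)
  expect_equal(scenes[[1]]$truth$x0, scenes[[2]]$truth$x0)
  expect_equal(scenes[[1]]$truth$y0, scenes[[2]]$truth$y0)
  r1 <- mean(scenes[[1]]$truth$cnr_true, na.rm = TRUE)
  r2 <- mean(scenes[[2]]$truth$cnr_true, na.rm = TRUE)
  expect_equal(r1, 4, tolerance = 0.05)
  expect_equal(r2, 8.7, tolerance = 0.05)
  # amplitude scaling is linear in CNR on a fixed background (noiseless)
  expect_gt(scenes[[2]]$truth$amplitude[1], scenes[[1]]$truth$amplitude[1])

  # doubling the amplitude doubles the realized noiseless CNR (up to the
  # small background term inside the signal maximum)
  p <- render_puncta_grid(c(128, 128), 9, amplitude = 200, sigma = 1.4,
                          arrangement = "grid")
  bg <- synth_background(c(128, 128), rng_seed = 33)
  cnr_of <- function(mult) {
    img <- mult * p$image
    sc <- compose_scene(bg, list(image = img, noiseless = img,
                                 truth = p$truth, masks = p$masks))
    mean(sc$truth$cnr_true, na.rm = TRUE)
  }
  expect_equal(cnr_of(2) / cnr_of(1), 2, tolerance = 0.05)

  expect_error(scene_series_by_cnr(c(64, 64), -1, n_puncta = 4),
               class = "rasp_validation_error")
  # constant background cannot realize any CNR
  expect_error(scene_series_by_cnr(c(96, 96), 5, n_puncta = 4,
                                   background = matrix(10, 96, 96)),
               class = "rasp_validation_error")
})
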