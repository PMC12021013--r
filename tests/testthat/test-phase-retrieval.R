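test_that("mean equalization shifts both images to the average of the means", {
  cfg <- default_config()
  # constant images: forced result
  p <- equalize_pair(defocus_pair(matrix(100, 8, 8), matrix(102, 8, 8), cfg))
  expect_equal(p$bf1, matrix(101, 8, 8))
  expect_equal(p$bf2, matrix(101, 8, 8))
  # identical pair is a fixed point
  b <- matrix_with_mean(1000, 16, 16, seed = 3)
  q <- equalize_pair(defocus_pair(b, b, cfg))
  expect_equal(q$bf1, b)
  expect_equal(q$bf2, b)
  # random pair with prescribed means 980.2 / 1013.7 -> both exactly 996.95
  r <- equalize_pair(defocus_pair(matrix_with_mean(980.2, 32, 32, seed = 4),
                                  matrix_with_mean(1013.7, 32, 32, seed = 5),
                                  cfg))
  expect_equal(mean(r$bf1), 996.95)
  expect_equal(mean(r$bf2), 996.95)
  # input pair untouched
  p0 <- defocus_pair(matrix(1, 4, 4), matrix(3, 4, 4), cfg)
  invisible(equalize_pair(p0))
  expect_equal(p0$bf1, matrix(1, 4, 4))
})

test_that("pair construction rejects mismatched shapes", {
  cfg <- default_config()
  expect_error(defocus_pair(matrix(1, 4, 4), matrix(1, 4, 5), cfg),
               "identical dimensions")
})

test_that("a featureless pair reconstructs to exactly zero phase", {
  pair <- defocus_pair(matrix(1000, 64, 64), matrix(1000, 64, 64),
                       default_config())
  tm <- solve_tie(pair, eps = 0)
  expect_equal(tm$values, matrix(0, 62, 62))
})

test_that("solver output is 2 px smaller per dimension and has zero mean", {
  phi <- gaussian_cell_phase(shape = c(96L, 128L))
  tm <- solve_tie(forward_tie_pair(phi, 1000, default_config()))
  expect_identical(dim(tm$values), c(94L, 126L))
  expect_equal(mean(tm$values), 0)
})

test_that("forward/inverse TIE round trip is exact at eps = 0", {
  phi <- gaussian_cell_phase(peak_phase = 1, sigma_um = 3)
  pair <- forward_tie_pair(phi, 1000, default_config())
  tm <- solve_tie(pair, eps = 0)
  truth <- phi$values[2:255, 2:255]
  truth <- truth - mean(truth)
  rel_l2 <- sqrt(sum((tm$values - truth)^2) / sum(truth^2))
  expect_lt(rel_l2, 1e-6)
})

test_that("a constant offset on one image is removed from the difference", {
  # equalization splits the +50 offset evenly, leaving the image difference
  # untouched; only the mean intensity in the denominator rises by 25, a
  # uniform gain of I0/(I0+25) absorbed by the empirical calibration
  phi <- gaussian_cell_phase(sigma_um = 4, shape = c(128L, 128L))
  cfg <- default_config()
  pair <- forward_tie_pair(phi, 1000, cfg)
  shifted <- defocus_pair(pair$bf1 + 50, pair$bf2, cfg)
  eq <- equalize_pair(shifted)
  expect_equal(eq$bf1 - eq$bf2, pair$bf1 - pair$bf2, tolerance = 1e-8)
  expect_equal(solve_tie(shifted, eps = 0)$values * (1025 / 1000),
               solve_tie(pair, eps = 0)$values, tolerance = 1e-9)
})

test_that("reconstruction is linear in the intensity difference at eps = 0", {
  cfg <- default_config()
  phi <- gaussian_cell_phase(sigma_um = 4, shape = c(96L, 96L))
  pair <- forward_tie_pair(phi, 1000, cfg)
  ibar <- (pair$bf1 + pair$bf2) / 2
  a <- 2.5    # scale the difference about the pixelwise mean
  scaled <- defocus_pair(ibar + a * (pair$bf1 - ibar),
                         ibar + a * (pair$bf2 - ibar), cfg)
  expect_equal(solve_tie(scaled, eps = 0)$values,
               a * solve_tie(pair, eps = 0)$values, tolerance = 1e-10)
})

test_that("the mounting-medium index has no effect on the reconstruction", {
  phi <- gaussian_cell_phase(sigma_um = 4, shape = c(96L, 96L))
  t1 <- solve_tie(forward_tie_pair(phi, 1000,
                                   default_config(n_medium = 1.337)))
  t2 <- solve_tie(forward_tie_pair(phi, 1000,
                                   default_config(n_medium = 1.5)))
  expect_identical(t1$values, t2$values)
})

test_that("damping eps > 0 suppresses but does not redirect the response", {
  phi <- gaussian_cell_phase(sigma_um = 4, shape = c(96L, 96L))
  pair <- forward_tie_pair(phi, 1000, default_config())
  t0 <- solve_tie(pair, eps = 0)
  t1 <- solve_tie(pair, eps = 1e-3)
  # damped reconstruction has strictly less energy, same sign structure
  expect_lt(sum(t1$values^2), sum(t0$values^2))
  expect_gt(stats::cor(as.vector(t0$values), as.vector(t1$values)), 0.9)
  expect_error(solve_tie(pair, eps = -1), "non-negative")
})

test_that("dark level is subtracted before reconstruction", {
  cfg_dark <- default_config(dark_level = 100)
  phi <- gaussian_cell_phase(sigma_um = 4, shape = c(96L, 96L))
  pair_dark <- forward_tie_pair(phi, 1000, cfg_dark)  # adds dark back
  pair_clean <- forward_tie_pair(phi, 1000, default_config())
  expect_equal(solve_tie(pair_dark, eps = 0)$values,
               solve_tie(pair_clean, eps = 0)$values, tolerance = 1e-9)
})

test_that("degenerate all-dark input is rejected", {
  cfg <- default_config(dark_level = 500)
  pair <- defocus_pair(matrix(500, 16, 16), matrix(500, 16, 16), cfg)
  expect_error(solve_tie(pair), "degenerate")
})

test_that("ROI integrals are background-corrected and gauge-invariant", {
  rois <- disk_rois(c(64L, 64L), 5)
  zero <- phase_map(matrix(0, 64, 64), 0.3)
  expect_equal(roi_integrated_phase(zero, rois)$integral_T, 0)
  # constant field: background subtraction cancels it
  const <- phase_map(matrix(3.7, 64, 64), 0.3)
  expect_equal(roi_integrated_phase(const, rois)$integral_T, 0)
  # adding a constant to a structured field changes nothing
  phi <- gaussian_cell_phase(shape = c(64L, 64L), sigma_um = 2)
  r1 <- roi_integrated_phase(phi, rois)
  r2 <- roi_integrated_phase(phase_map(phi$values + 11.3, 0.3), rois)
  expect_equal(r1$integral_T, r2$integral_T)
  # requesting an absent label warns and skips
  expect_warning(out <- roi_integrated_phase(phi, rois, labels = c(1L, 9L)),
                 "empty ROI")
  expect_identical(out$label, 1L)
})

test_that("reconstructed bead integral matches the analytic sphere phase", {
  cfg <- default_config()
  bp <- bead_phase_map(7.7, 0.05, cfg$wavelength_um, cfg$pixel_size_um)
  tm <- solve_tie(forward_tie_pair(bp, 1000, cfg), eps = 0)
  rois <- trim_rois(disk_rois(c(256L, 256L), 5.5))
  got <- roi_integrated_phase(tm, rois)$integral_T
  expected <- 2 * pi / cfg$wavelength_um * 0.05 * sphere_volume(7.7)
  expect_lt(abs(got / expected - 1), 0.02)
  expect_gt(got, 0)   # positive-index bead must integrate positive
})
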