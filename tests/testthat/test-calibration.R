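test_that("sphere volume matches the nominal calibration-bead volume", {
  expect_equal(signif(sphere_volume(7.7), 3), 239)
  expect_equal(sphere_volume(0), 0)
  expect_equal(sphere_volume(2), 4.18879, tolerance = 1e-6)
  expect_error(sphere_volume(-1), ">= 0")
})

test_that("ideal-solver coefficient is 0.86 lambda", {
  expect_equal(round(1 / (2 * pi * 0.185), 2), 0.86)
  expect_equal(theoretical_s(0.486), 0.4181, tolerance = 1e-4)
  expect_error(theoretical_s(0), "positive")
})

test_that("bead regression recovers an exactly linear construction", {
  g0 <- 2 * pi / 0.486
  v <- sphere_volume(7.7)
  oils <- c(1.35, 1.39, 1.44, 1.48, 1.52)
  obs <- data.frame(n_oil = oils, t_bead = v * g0 * (1.43 - oils))
  fit <- fit_bead_calibration(obs, v_bead_um3 = v, n_bead = 1.43)
  expect_equal(fit$g, g0, tolerance = 1e-12)
  expect_equal(fit$s, 1 / (0.185 * g0), tolerance = 1e-12)
  expect_equal(fit$s, 0.86 * 0.486, tolerance = 2e-3)
  expect_equal(fit$r_squared, 1)
})

test_that("two observations give an exact interpolating line", {
  obs <- data.frame(n_oil = c(1.40, 1.50), t_bead = c(500, -300))
  fit <- fit_bead_calibration(obs, v_bead_um3 = 239)
  pred <- stats::predict(fit$fit, data.frame(n_oil = obs$n_oil))
  expect_equal(unname(pred), obs$t_bead / 239, tolerance = 1e-12)
})

test_that("bead regression tolerates observation noise", {
  g0 <- 2 * pi / 0.486
  v <- sphere_volume(7.7)
  oils <- c(1.35, 1.38, 1.41, 1.44, 1.47, 1.50)
  clean <- v * g0 * (1.43 - oils)
  noisy <- clean + with_seed_test(42,
    stats::rnorm(length(oils), sd = 0.02 * diff(range(clean))))
  fit <- fit_bead_calibration(data.frame(n_oil = oils, t_bead = noisy), v)
  expect_lt(abs(fit$g / g0 - 1), 0.05)
})

test_that("per-group integrals are normalized by the bead count", {
  g0 <- 2 * pi / 0.486
  v <- sphere_volume(7.7)
  oils <- c(1.36, 1.40, 1.46, 1.50)
  n <- c(1L, 3L, 2L, 4L)
  obs <- data.frame(n_oil = oils, t_bead = n * v * g0 * (1.43 - oils),
                    n_beads = n)
  fit <- fit_bead_calibration(obs, v)
  expect_equal(fit$g, g0, tolerance = 1e-12)
})

test_that("raw measurement columns are accepted in place of t_bead", {
  obs <- data.frame(n_oil = c(1.40, 1.46), area_um2 = c(90, 110),
                    mean_T = c(2.0, -1.0), bkg_T = c(0.1, 0.1))
  fit <- fit_bead_calibration(obs, 239)
  expect_equal(fit$data$t_bead, c(90 * 1.9, 110 * -1.1))
})

test_that("degenerate or sign-flipped bead data is rejected", {
  expect_error(fit_bead_calibration(
    data.frame(n_oil = c(1.4, 1.4), t_bead = c(1, 2)), 239),
    "2 distinct")
  expect_error(fit_bead_calibration(
    data.frame(n_oil = c(1.40, 1.50), t_bead = c(-300, 500)), 239),
    "swapped")
})

test_that("s and g satisfy their exact duality for every fit", {
  for (seed in 1:4) {
    oils <- c(1.35, 1.41, 1.47, 1.53)
    tb <- with_seed_test(seed, 239 * (10 * (1.43 - oils) +
                                        stats::rnorm(4, sd = 0.3)))
    fit <- try(fit_bead_calibration(data.frame(n_oil = oils, t_bead = tb),
                                    239), silent = TRUE)
    if (!inherits(fit, "try-error"))
      expect_equal(fit$s * 0.185 * fit$g, 1, tolerance = 1e-12)
  }
})

test_that("end-to-end synthetic calibration recovers the ideal coefficient", {
  fit <- run_synthetic_bead_calibration(n_oils = c(1.33, 1.38, 1.41, 1.48))
  expect_lt(abs(fit$s / theoretical_s(0.486) - 1), 0.05)
  expect_gt(fit$r_squared, 0.999)
})

test_that("half-ball depth follows the chord geometry", {
  lens <- lens_geometry(5000)
  expect_equal(halfball_depth(0, lens), 0)
  expect_equal(halfball_depth(3000, lens), 1000)   # 3-4-5 triangle
  expect_equal(halfball_depth(5000, lens), 5000)
  expect_error(halfball_depth(5001, lens), "exceeds")
  d <- seq(0, 5000, by = 50)
  expect_true(all(diff(halfball_depth(d, lens)) > 0))  # monotone
})

test_that("radial profile averages annuli correctly", {
  # uniform image -> constant profile
  prof <- radial_profile(matrix(7, 64, 64), c(32, 32))
  expect_true(all(prof$intensity == 7))
  # single bright centre pixel lifts only the first bin
  img <- matrix(100, 33, 33); img[17, 17] <- 1100
  prof2 <- radial_profile(img, c(17, 17))
  expect_equal(prof2$intensity[1], 1100)
  expect_true(all(prof2$intensity[-1] == 100))
  # pixel size scales reported radii
  prof3 <- radial_profile(matrix(1, 16, 16), c(8, 8), pixel_size_um = 2)
  expect_equal(prof3$radius_um,
               2 * radial_profile(matrix(1, 16, 16), c(8, 8))$radius_um)
  expect_error(radial_profile(matrix(1, 8, 8), c(0, 4)), "inside")
})

test_that("log radial profile of a synthetic half-ball is linear in depth", {
  hb <- halfball_image(0.15, lens_geometry(5000), i0 = 3000,
                       pixel_size_um = 4, shape = c(128L, 128L))
  # centre is the brightest pixel, corners the dimmest
  expect_equal(max(hb$image), hb$image[64, 64])
  expect_equal(min(hb$image), hb$image[1, 1])
  prof <- radial_profile(hb$image, hb$center, pixel_size_um = 4)
  h <- halfball_depth(prof$radius_um, lens_geometry(5000))
  fit <- stats::lm(log(prof$intensity) ~ h)
  expect_equal(-unname(stats::coef(fit)[2]), 0.15, tolerance = 1e-3)
})

test_that("absorption fit recovers alpha from a synthetic half-ball image", {
  hb <- halfball_image(0.15, lens_geometry(5000), i0 = 3000,
                       pixel_size_um = 4)
  prof <- radial_profile(hb$image, hb$center, pixel_size_um = 4)
  fit <- fit_absorption(prof, lens_geometry(5000))
  expect_lt(abs(fit$alpha_per_um / 0.15 - 1), 0.001)
  expect_gte(fit$r_squared, 0.9999)
  # global intensity scaling leaves alpha untouched
  prof2 <- prof; prof2$intensity <- prof2$intensity * 5.5
  fit2 <- fit_absorption(prof2, lens_geometry(5000))
  expect_equal(fit2$alpha_per_um, fit$alpha_per_um, tolerance = 1e-12)
})

test_that("absorption fit handles noise, constants and bad data", {
  hb <- halfball_image(0.15, lens_geometry(5000), i0 = 3000,
                       pixel_size_um = 4,
                       noise = noise_model("gaussian", sd = 0.005),
                       seed = 11)
  prof <- radial_profile(hb$image, hb$center, pixel_size_um = 4)
  fit <- suppressWarnings(fit_absorption(prof, lens_geometry(5000)))
  expect_lt(abs(fit$alpha_per_um / 0.15 - 1), 0.02)
  # constant profile: alpha 0, undefined R^2, flagged
  flat <- data.frame(radius_um = seq(300, 2000, by = 50), intensity = 500)
  expect_warning(f0 <- fit_absorption(flat, lens_geometry(5000)),
                 "constant")
  expect_equal(f0$alpha_per_um, 0)
  expect_true(is.na(f0$r_squared))
  # too few points
  expect_error(fit_absorption(data.frame(radius_um = c(400, 600, 800),
                                         intensity = c(3, 2, 1)),
                              lens_geometry(5000)), "10 usable")
  # low-quality fit warns but returns
  bent <- data.frame(radius_um = seq(300, 2000, by = 50))
  bent$intensity <- 3000 * exp(-0.15 * halfball_depth(bent$radius_um,
                                                      lens_geometry(5000)))^0.5 +
    0.2 * seq_len(nrow(bent))^2
  expect_warning(fit_absorption(bent, lens_geometry(5000)), "quality")
})
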