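#' Volume of a sphere from its diameter
#'
#' Mean bead volume used to normalize integrated phase per bead; for the
#' standard 7.7-um silica calibration beads this is 239 um^3.
#'
#' @param diameter_um Sphere diameter in micrometres (>= 0, vectorized).
#' @return Volume in um^3, (pi/6) d^3.
#' @examples
#' sphere_volume(7.7)  # ~239
#' @export
sphere_volume <- function(diameter_um) {
  if (any(diameter_um < 0)) stop("'diameter_um' must be >= 0")
  pi / 6 * diameter_um^3
}

#' Ideal-solver phase-to-concentration coefficient
#'
#' For an exact (uncalibrated, undamped) TIE inversion the coefficient that
#' converts integrated phase per volume into protein concentration is
#' s = lambda / (2 pi 0.185) = 0.86 lambda. Practical solvers damp the
#' inverse Laplacian and need the empirical s from bead calibration; this
#' value is the sanity reference the empirical fit is compared against.
#'
#' @param wavelength_um Vacuum wavelength in micrometres (> 0).
#' @return s in micrometres.
#' @examples
#' theoretical_s(0.486)  # ~0.418 um
#' @export
theoretical_s <- function(wavelength_um) {
  if (any(wavelength_um <= 0)) stop("'wavelength_um' must be positive")
  wavelength_um / (2 * pi * physical_constants()$refractive_increment)
}

#' Bead-in-oil calibration of the TIE coefficient s
#'
#' Silica beads of known mean volume are immersed in a series of oils of
#' known refractive index and imaged as defocus pairs; the background-
#' corrected integrated phase per bead, divided by the mean bead volume,
#' is regressed on the oil index:
#' \deqn{T_{bead}/V_{bead} = k (n_{bead} - n_{oil}) = g\,\Delta n,}
#' so the fitted slope is -g. The empirical conversion coefficient follows
#' as s = 1 / (0.185 g). A non-positive g indicates a sign-convention error
#' (overfocused and underfocused images swapped).
#'
#' @param obs Data frame of bead observations with columns `n_oil` and
#'   either `t_bead` (corrected integrated phase per group, phase um^2) or
#'   the raw measurement columns `area_um2`, `mean_T`, `bkg_T` from which
#'   `t_bead = area_um2 * (mean_T - bkg_T)` is computed; optional column
#'   `n_beads` (beads per group, default 1) divides the group integral.
#' @param v_bead_um3 Mean bead volume in um^3 (e.g. `sphere_volume(7.7)`).
#' @param n_bead Refractive index of the bead material (metadata; enters
#'   only through the intercept, not the fitted slope).
#' @return An object of class `"bead_calibration"` with elements `k`, `g`,
#'   `s` (um), `r_squared`, `n_bead`, `v_bead_um3`, the underlying `lm` fit
#'   and the per-bead data.
#' @examples
#' g0 <- 2 * pi / 0.486
#' obs <- data.frame(n_oil = c(1.38, 1.40, 1.44, 1.48),
#'                   t_bead = 239 * g0 * (1.43 - c(1.38, 1.40, 1.44, 1.48)))
#' fit <- fit_bead_calibration(obs, v_bead_um3 = 239, n_bead = 1.43)
#' fit$s  # ~0.418 = 0.86 * 0.486
#' @export
fit_bead_calibration <- function(obs, v_bead_um3, n_bead = NA_real_) {
  obs <- as.data.frame(obs)
  if (!("n_oil" %in% names(obs))) stop("'obs' must have a column 'n_oil'")
  if (!("t_bead" %in% names(obs))) {
    need <- c("area_um2", "mean_T", "bkg_T")
    if (!all(need %in% names(obs)))
      stop("'obs' needs either 't_bead' or columns ",
           paste(need, collapse = ", "))
    obs$t_bead <- obs$area_um2 * (obs$mean_T - obs$bkg_T)
  }
  if (is.null(obs$n_beads)) obs$n_beads <- 1L
  if (any(obs$n_beads < 1)) stop("'n_beads' must be >= 1")
  if (v_bead_um3 <= 0) stop("'v_bead_um3' must be positive")
  if (length(unique(obs$n_oil)) < 2L)
    stop("calibration needs at least 2 distinct oil refractive indices")

  obs$t_per_bead <- obs$t_bead / obs$n_beads
  obs$response <- obs$t_per_bead / v_bead_um3
  fit <- stats::lm(response ~ n_oil, data = obs)
  slope <- unname(stats::coef(fit)[2])
  g <- -slope
  if (g <= 0)
    stop("fitted g <= 0: integrated phase increases with oil index; ",
         "over/underfocused images are likely swapped")
  # direct R^2: summary.lm warns on exact synthetic data
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((obs$response - mean(obs$response))^2)
  inc <- physical_constants()$refractive_increment
  structure(list(k = g, g = g, s = 1 / (inc * g), r_squared = r2,
                 n_bead = n_bead, v_bead_um3 = v_bead_um3,
                 fit = fit, data = obs),
            class = "bead_calibration")
}

#' @export
print.bead_calibration <- function(x, ...) {
  cat("Bead-in-oil TIE calibration\n")
  cat(sprintf("  groups: %d over %d oils, v_bead = %.4g um^3\n",
              nrow(x$data), length(unique(x$data$n_oil)), x$v_bead_um3))
  cat(sprintf("  g  = %.6g per unit index per um^3\n", x$g))
  cat(sprintf("  s  = %.6g um   (ideal solver at 0.486 um: %.4g um)\n",
              x$s, theoretical_s(0.486)))
  cat(sprintf("  R^2 = %.6f\n", x$r_squared))
  invisible(x)
}

#' @export
coef.bead_calibration <- function(object, ...) {
  c(g = object$g, s = object$s)
}

#' @export
summary.bead_calibration <- function(object, ...) {
  s <- summary(object$fit)
  cat("Underlying regression of T_bead / V_bead on n_oil:\n")
  print(s)
  invisible(s)
}

#' @export
plot.bead_calibration <- function(x, ...) {
  graphics::plot(x$data$n_oil, x$data$response,
                 xlab = "oil refractive index (486 nm)",
                 ylab = expression(T[bead] / V[bead]),
                 main = "Bead-in-oil TIE calibration", ...)
  graphics::abline(x$fit, col = "steelblue")
  invisible(x)
}

#' Half-ball lens geometry
#'
#' Geometry of the plano-convex half-ball lens resting on a slide in a drop
#' of dye, used to measure the dye absorption coefficient: the dye layer
#' depth grows with distance from the touch point.
#'
#' @param radius_um Lens radius in micrometres (default 5000, a 5-mm lens).
#' @param center Optional pixel coordinates `c(row, col)` of the touch point.
#' @return An object of class `"lens_geometry"`.
#' @export
lens_geometry <- function(radius_um = 5000, center = NULL) {
  if (radius_um <= 0) stop("'radius_um' must be positive")
  structure(list(radius_um = radius_um, center = center),
            class = "lens_geometry")
}

#' Dye-layer depth under a half-ball lens
#'
#' At radial distance d from the touch point of a half-ball lens of radius R
#' the depth of the liquid layer between lens and slide is
#' h = R - sqrt(R^2 - d^2).
#'
#' @param d_um Radial distance(s) from the touch point in micrometres,
#'   0 <= d <= R.
#' @param lens A [lens_geometry()] (or a single numeric radius in um).
#' @return Depth(s) in micrometres.
#' @examples
#' halfball_depth(3000, lens_geometry(5000))  # 1000 (3-4-5 triangle)
#' @export
halfball_depth <- function(d_um, lens = lens_geometry()) {
  r <- if (inherits(lens, "lens_geometry")) lens$radius_um else lens
  if (any(d_um < 0)) stop("'d_um' must be >= 0")
  if (any(d_um > r)) stop("'d_um' exceeds the lens radius")
  r - sqrt(r^2 - d_um^2)
}

#' Radial intensity profile about a point
#'
#' Annular means of image intensity in concentric bins about a centre pixel,
#' the digital equivalent of the radial-profile step of the half-ball
#' measurement. Radii are reported in micrometres.
#'
#' @param image Numeric matrix of intensity counts.
#' @param center Pixel coordinates `c(row, col)` of the profile centre; must
#'   lie inside the image.
#' @param bin_width_px Bin width in pixels (default 1).
#' @param pixel_size_um Pixel size in micrometres (default 1).
#' @return Data frame with `radius_um` (mean pixel radius per bin),
#'   `intensity` (annular mean) and `n_pixels`.
#' @export
radial_profile <- function(image, center, bin_width_px = 1,
                           pixel_size_um = 1) {
  image <- as_image_matrix(image, "image")
  if (length(center) != 2L || center[1] < 1 || center[1] > nrow(image) ||
      center[2] < 1 || center[2] > ncol(image))
    stop("'center' must be pixel coordinates c(row, col) inside the image")
  if (bin_width_px <= 0) stop("'bin_width_px' must be positive")
  rr <- sqrt(outer((seq_len(nrow(image)) - center[1])^2,
                   (seq_len(ncol(image)) - center[2])^2, "+"))
  bin <- floor(rr / bin_width_px)
  r_mean <- tapply(rr, bin, mean) * pixel_size_um
  i_mean <- tapply(image, bin, mean)
  n_px <- tapply(rep(1, length(bin)), bin, sum)
  data.frame(radius_um = as.numeric(r_mean),
             intensity = as.numeric(i_mean),
             n_pixels = as.numeric(n_px), row.names = NULL)
}

#' Fit the dye absorption coefficient from a half-ball radial profile
#'
#' Converts profile radii into dye-layer depths via [halfball_depth()] and
#' fits the Beer-Lambert line ln(I - dark) = ln(I0) - alpha h by ordinary
#' least squares; alpha is minus the slope. The innermost points (default:
#' radii within 5% of the lens radius, where the shallow depths are least
#' reliable) and the final profile point (an artifact of the standard
#' radial-profile plugin) are excluded. A fit with R^2 below the quality
#' threshold triggers a warning, not an error.
#'
#' @param profile Data frame from [radial_profile()] (columns `radius_um`,
#'   `intensity`).
#' @param lens A [lens_geometry()].
#' @param dark Dark counts subtracted from intensities before the log.
#' @param inner_exclusion_frac Fraction of the lens radius below which
#'   points are dropped (default 0.05).
#' @param r2_threshold Quality gate on R^2 (default 0.9999).
#' @return An object of class `"absorption_fit"` with `alpha_per_um`,
#'   `r_squared`, `n_points`, the `lm` fit and the fitted subset.
#' @export
fit_absorption <- function(profile, lens = lens_geometry(), dark = 0,
                           inner_exclusion_frac = 0.05,
                           r2_threshold = 0.9999) {
  profile <- as.data.frame(profile)
  stopifnot(all(c("radius_um", "intensity") %in% names(profile)))
  p <- profile[-nrow(profile), , drop = FALSE]       # last bin is unreliable
  p <- p[p$radius_um >= inner_exclusion_frac * lens$radius_um, , drop = FALSE]
  p <- p[p$radius_um <= lens$radius_um, , drop = FALSE]
  if (nrow(p) < 10L)
    stop("fewer than 10 usable profile points after exclusions")
  v <- p$intensity - dark
  if (any(v <= 0)) stop("intensities must exceed the dark level")
  p$depth_um <- halfball_depth(p$radius_um, lens)
  p$ln_intensity <- log(v)
  if (stats::var(p$ln_intensity) == 0) {
    warning("constant profile: absorption coefficient is 0, R^2 undefined")
    return(structure(list(alpha_per_um = 0, r_squared = NA_real_,
                          n_points = nrow(p), fit = NULL, data = p),
                     class = "absorption_fit"))
  }
  fit <- stats::lm(ln_intensity ~ depth_um, data = p)
  alpha <- -unname(stats::coef(fit)[2])
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((p$ln_intensity - mean(p$ln_intensity))^2)
  if (r2 < r2_threshold)
    warning(sprintf("absorption fit R^2 = %.6f below quality threshold %.4f",
                    r2, r2_threshold))
  structure(list(alpha_per_um = alpha, r_squared = r2, n_points = nrow(p),
                 fit = fit, data = p),
            class = "absorption_fit")
}

#' @export
print.absorption_fit <- function(x, ...) {
  cat(sprintf("Beer-Lambert absorption fit: alpha = %.6g /um (R^2 = %s, n = %d)\n",
              x$alpha_per_um, format(x$r_squared), x$n_points))
  invisible(x)
}

#' @export
coef.absorption_fit <- function(object, ...) {
  c(alpha_per_um = object$alpha_per_um)
}

#' @export
residuals.absorption_fit <- function(object, ...) {
  if (is.null(object$fit)) return(numeric(0))
  stats::residuals(object$fit)
}

#' @export
plot.absorption_fit <- function(x, ...) {
  graphics::plot(x$data$depth_um, x$data$ln_intensity,
                 xlab = "dye-layer depth h (um)", ylab = "ln(I - dark)",
                 main = "Half-ball absorption fit", ...)
  if (!is.null(x$fit)) graphics::abline(x$fit, col = "firebrick")
  invisible(x)
}
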