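#' Synthetic phantoms and forward models
#'
#' The generators in this file render known ground truth into the same image
#' formats the measurement functions consume: phase objects into defocused
#' brightfield pairs (the forward form of the transport-of-intensity
#' relation, using the package's own discrete Laplacian so that
#' [solve_tie()] at `eps = 0` is its exact inverse), height fields into
#' dye-exclusion images via the Beer-Lambert law, and the half-ball-lens
#' absorption geometry. All noise is applied after the clean render and is
#' deterministic given a seed.
#'
#' @name synthetic
NULL

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state; seed = NULL leaves the RNG alone entirely.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Noise model specification
#'
#' Noise for the synthetic generators: `"gaussian"` is multiplicative with
#' `sd` a fraction of the local intensity (camera noise is naturally
#' quantified as relative pixel noise dI/I); `"poisson"` draws
#' `rpois(I * scale) / scale`, i.e. `scale` photoelectrons per count.
#'
#' @param type One of `"gaussian"` or `"poisson"`.
#' @param sd Fractional standard deviation (gaussian).
#' @param scale Photoelectrons per count (poisson).
#' @return A noise-model list, or `NULL` for no noise.
#' @export
noise_model <- function(type = c("gaussian", "poisson"), sd = 0.01,
                        scale = 1) {
  type <- match.arg(type)
  if (type == "gaussian" && sd < 0) stop("'sd' must be >= 0")
  if (type == "poisson" && scale <= 0) stop("'scale' must be positive")
  list(type = type, sd = sd, scale = scale)
}

apply_noise <- function(img, noise, seed = NULL) {
  if (is.null(noise)) return(img)
  with_seed(seed, {
    switch(noise$type,
           gaussian = img * (1 + stats::rnorm(length(img), sd = noise$sd)),
           poisson = stats::rpois(length(img), pmax(img, 0) * noise$scale) /
             noise$scale,
           stop("unknown noise type")) |>
      matrix(nrow = nrow(img))
  })
}

#' Phase map of a homogeneous spherical bead
#'
#' The optical phase of a sphere of diameter d and index elevation
#' delta_n over the surrounding oil is proportional to the chord length:
#' phi(x, y) = (2 pi / lambda) delta_n 2 sqrt(r^2 - rho^2) inside the
#' outline and 0 outside. Its field integral is (2 pi / lambda) delta_n
#' times the sphere volume, the analytic anchor of the bead calibration.
#'
#' @param diameter_um Bead diameter in um; must fit inside the field.
#' @param delta_n Index elevation of the bead over the oil (may be negative
#'   for oils denser than the bead).
#' @param wavelength_um Vacuum wavelength in um.
#' @param pixel_size_um Pixel size in um (default 0.3).
#' @param shape Image dimensions `c(rows, cols)` (default 256 x 256).
#' @param center Bead centre in pixel coordinates (default image centre).
#' @return A [phase_map()].
#' @export
bead_phase_map <- function(diameter_um, delta_n, wavelength_um,
                           pixel_size_um = 0.3, shape = c(256L, 256L),
                           center = NULL) {
  if (diameter_um <= 0) stop("'diameter_um' must be positive")
  if (diameter_um > min(shape) * pixel_size_um)
    stop("bead does not fit inside the field")
  if (is.null(center)) center <- (shape + 1) / 2
  r <- diameter_um / 2
  rho2 <- outer(((seq_len(shape[1]) - center[1]) * pixel_size_um)^2,
                ((seq_len(shape[2]) - center[2]) * pixel_size_um)^2, "+")
  chord <- 2 * sqrt(pmax(r^2 - rho2, 0))
  phase_map(2 * pi / wavelength_um * delta_n * chord, pixel_size_um)
}

#' Smooth Gaussian phase phantom
#'
#' A cell-like smooth phase bump, phi = peak * exp(-rho^2 / (2 sigma^2)).
#' Smoothness makes it the reference object for the forward/inverse TIE
#' round-trip oracle.
#'
#' @param peak_phase Peak phase in radians (default 1).
#' @param sigma_um Gaussian width in um (default 6).
#' @param pixel_size_um Pixel size in um (default 0.3).
#' @param shape Image dimensions (default 256 x 256).
#' @param center Centre in pixel coordinates (default image centre).
#' @return A [phase_map()].
#' @export
gaussian_cell_phase <- function(peak_phase = 1, sigma_um = 6,
                                pixel_size_um = 0.3, shape = c(256L, 256L),
                                center = NULL) {
  if (sigma_um <= 0) stop("'sigma_um' must be positive")
  if (is.null(center)) center <- (shape + 1) / 2
  rho2 <- outer(((seq_len(shape[1]) - center[1]) * pixel_size_um)^2,
                ((seq_len(shape[2]) - center[2]) * pixel_size_um)^2, "+")
  phase_map(peak_phase * exp(-rho2 / (2 * sigma_um^2)), pixel_size_um)
}

#' Height field of a dome-shaped (half-ellipsoid) cell
#'
#' An adherent-cell-like cap: h(rho) = h0 sqrt(1 - (rho/a)^2) for rho < a,
#' 0 outside, with analytic volume (2/3) pi a^2 h0. Used as joint ground
#' truth for the phase and dye-exclusion channels in end-to-end tests.
#'
#' @param base_radius_um Footprint radius a in um.
#' @param height_um Apex height h0 in um.
#' @param pixel_size_um Pixel size in um (default 0.3).
#' @param shape Image dimensions (default 256 x 256).
#' @param center Centre in pixel coordinates (default image centre).
#' @return A list of class `"height_map"`; attribute `volume_um3` holds the
#'   analytic cap volume.
#' @export
cap_cell_height <- function(base_radius_um, height_um, pixel_size_um = 0.3,
                            shape = c(256L, 256L), center = NULL) {
  if (base_radius_um <= 0 || height_um <= 0)
    stop("'base_radius_um' and 'height_um' must be positive")
  if (2 * base_radius_um > min(shape) * pixel_size_um)
    stop("cell does not fit inside the field")
  if (is.null(center)) center <- (shape + 1) / 2
  rho2 <- outer(((seq_len(shape[1]) - center[1]) * pixel_size_um)^2,
                ((seq_len(shape[2]) - center[2]) * pixel_size_um)^2, "+")
  h <- height_um * sqrt(pmax(1 - rho2 / base_radius_um^2, 0))
  structure(list(values = h, pixel_size_um = pixel_size_um),
            class = "height_map",
            volume_um3 = 2 / 3 * pi * base_radius_um^2 * height_um)
}

#' Render a phase object into a defocused brightfield pair
#'
#' Forward model of defocused brightfield contrast: the intensity difference
#' between the two planes is set by the transverse Laplacian of the phase,
#' \deqn{BF_{1,2} = I_0\,(1 \pm c/2),\quad
#'       c = -\frac{\lambda\,\Delta z'}{2\pi\,n_{imm}}\,\nabla^2\phi,}
#' using the same 5-point discrete Laplacian as [solve_tie()], which makes
#' the forward/inverse pair exact at `eps = 0`. The configured dark level is
#' added back so the rendered pair is consistent with its own config.
#' Contrast magnitudes above 1 would require negative intensities and raise
#' an error suggesting a smaller defocus separation.
#'
#' @param phase A [phase_map()] (smooth relative to the pixel grid).
#' @param base_intensity Background intensity I0 in counts (> 0).
#' @param config An [optical_config()]; its `pixel_size_um` must match the
#'   phase map.
#' @param noise A [noise_model()] or `NULL`.
#' @param seed RNG seed for the noise draw.
#' @return A [defocus_pair()].
#' @export
forward_tie_pair <- function(phase, base_intensity, config, noise = NULL,
                             seed = NULL) {
  stopifnot(inherits(phase, "phase_map"), inherits(config, "optical_config"))
  if (base_intensity <= 0) stop("'base_intensity' must be positive")
  if (abs(phase$pixel_size_um - config$pixel_size_um) > 1e-12)
    stop("pixel size of phase map and config disagree")
  lap <- discrete_laplacian(phase$values, config$pixel_size_um)
  contrast <- -(config$wavelength_um * config$dz_um /
                  (2 * pi * config$n_imm)) * lap
  if (max(abs(contrast)) > 1)
    stop(sprintf(paste0("unphysical contrast (|c| up to %.3g > 1): the ",
                        "defocus separation is too large for this object; ",
                        "reduce 'dz_um'"), max(abs(contrast))))
  bf1 <- base_intensity * (1 + contrast / 2)
  bf2 <- base_intensity * (1 - contrast / 2)
  bf1 <- apply_noise(bf1, noise, seed)
  bf2 <- apply_noise(bf2, noise, if (is.null(seed)) NULL else seed + 1L)
  defocus_pair(bf1 + config$dark_level, bf2 + config$dark_level, config)
}

#' Render a height field into a dye-exclusion image
#'
#' Inverse of [height_map()]: where the cell displaces the absorbing dye the
#' light path through dye shortens and the image brightens,
#' I = I_bkg exp(alpha h). The known background log intensity is recorded on
#' the returned image.
#'
#' @param h A `height_map` (values in um, >= 0).
#' @param alpha_per_um Dye absorption coefficient in 1/um (> 0).
#' @param bkg_intensity Background intensity in counts (> 0).
#' @param dark_level Dark counts added to the rendered image (default 0).
#' @param noise A [noise_model()] or `NULL`.
#' @param seed RNG seed for the noise draw.
#' @return A [ttd_image()].
#' @export
ttd_image_from_height <- function(h, alpha_per_um, bkg_intensity,
                                  dark_level = 0, noise = NULL, seed = NULL) {
  stopifnot(inherits(h, "height_map"))
  if (alpha_per_um <= 0) stop("'alpha_per_um' must be positive")
  if (bkg_intensity <= 0) stop("'bkg_intensity' must be positive")
  if (min(h$values) < 0) stop("height field must be non-negative")
  img <- bkg_intensity * exp(alpha_per_um * h$values)
  img <- apply_noise(img, noise, seed)
  ttd_image(img + dark_level, h$pixel_size_um, dark_level = dark_level,
            background_log_intensity = log(bkg_intensity))
}

#' Synthetic half-ball-lens absorption image
#'
#' Renders the radially symmetric intensity pattern around the touch point
#' of a half-ball lens in dye: I(d) = I0 exp(-alpha h(d)) with h(d) the
#' lens-slide gap of [halfball_depth()]. The centre is the brightest point
#' and intensity falls off with distance.
#'
#' @param alpha_per_um Dye absorption coefficient in 1/um (> 0).
#' @param lens A [lens_geometry()]; its `center` (pixel coords) defaults to
#'   the image centre.
#' @param i0 Intensity at the touch point, in counts.
#' @param pixel_size_um Pixel size in um.
#' @param shape Image dimensions (default 256 x 256).
#' @param noise A [noise_model()] or `NULL`.
#' @param seed RNG seed for the noise draw.
#' @return A list with `image` (matrix of counts), `center` and
#'   `pixel_size_um`.
#' @export
halfball_image <- function(alpha_per_um, lens = lens_geometry(), i0 = 3000,
                           pixel_size_um = 4, shape = c(256L, 256L),
                           noise = NULL, seed = NULL) {
  if (alpha_per_um <= 0) stop("'alpha_per_um' must be positive")
  center <- if (is.null(lens$center)) (shape + 1) / 2 else lens$center
  d_um <- sqrt(outer(((seq_len(shape[1]) - center[1]) * pixel_size_um)^2,
                     ((seq_len(shape[2]) - center[2]) * pixel_size_um)^2,
                     "+"))
  if (max(d_um) >= lens$radius_um)
    stop("image extends beyond the lens radius; use a smaller field or ",
         "pixel size")
  img <- i0 * exp(-alpha_per_um * halfball_depth(d_um, lens))
  img <- apply_noise(img, noise, seed)
  list(image = img, center = center, pixel_size_um = pixel_size_um)
}
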