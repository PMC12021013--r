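#' Equalize the mean intensities of a defocus pair
#'
#' TIE contrast lives in the small difference between the two defocused
#' images, so any global exposure mismatch between them turns directly into a
#' spurious phase background. Each image is shifted by half of the difference
#' of the means: BF1' = BF1 + (mean(BF2) - mean(BF1))/2 and symmetrically for
#' BF2, so both output means equal the average of the two input means.
#'
#' @param pair A [defocus_pair()].
#' @return A new `defocus_pair` with equalized means; the input is unchanged.
#' @examples
#' cfg <- optical_config(0.486, 1, 1, 0.3)
#' p <- defocus_pair(matrix(100, 8, 8), matrix(102, 8, 8), cfg)
#' q <- equalize_pair(p)
#' mean(q$bf1); mean(q$bf2)  # both 101
#' @export
equalize_pair <- function(pair) {
  stopifnot(inherits(pair, "defocus_pair"))
  m1 <- mean(pair$bf1)
  m2 <- mean(pair$bf2)
  pair$bf1 <- pair$bf1 + 0.5 * (m2 - m1)
  pair$bf2 <- pair$bf2 + 0.5 * (m1 - m2)
  pair
}

#' Solve the transport-of-intensity equation for a defocus pair
#'
#' Reconstructs the relative phase map T(x, y) from an overfocused /
#' underfocused brightfield pair. After dark-level subtraction and mean
#' equalization the axial intensity derivative is approximated by the image
#' difference, giving the Poisson problem
#' \deqn{-\nabla^2 T = \frac{2\pi\, n_{imm}}{\lambda}\,
#'       \frac{BF1' - BF2'}{\bar I\, \Delta z'},}
#' where the mean intensity \eqn{\bar I} is the pixelwise mean of the
#' equalized pair (floor-clamped at 1e-6 of its field mean). The Laplacian is
#' inverted in a spectral basis with mirror (Neumann-consistent) boundary
#' extension, exactly inverting the package's 5-point discrete Laplacian when
#' `eps = 0`. For `eps > 0` the inverse is damped by the factor
#' k^2/(k^2 + eps * k_max^2) on squared spatial frequency, which suppresses
#' the low-frequency noise amplification inherent in inverting a Laplacian
#' at the cost of biasing absolute phase values (hence the empirical
#' calibration coefficient, see [fit_bead_calibration()]).
#'
#' The refractive index of the mounting medium plays no role: it cancels
#' from the governing equation once the focal shift inside the sample is
#' accounted for. The returned map is trimmed by one pixel on every side
#' (the border rows/columns of an inverse-Laplacian reconstruction are the
#' least reliable), so it is 2 px smaller than the input in each dimension,
#' and is gauge-fixed to zero mean.
#'
#' @param pair A [defocus_pair()]; `pair$config$dark_level` is subtracted
#'   from both images first.
#' @param eps Non-negative Tikhonov-style damping factor on the squared
#'   spatial frequency. `0` gives the exact (undamped) inverse; default
#'   `1e-3` reproduces the denoising behaviour expected of practical TIE
#'   solvers.
#' @return A [phase_map()] of dimension (nrow-2) x (ncol-2).
#' @seealso [forward_tie_pair()] for the matching forward model,
#'   [roi_integrated_phase()] for background-corrected ROI integrals.
#' @export
solve_tie <- function(pair, eps = 1e-3) {
  stopifnot(inherits(pair, "defocus_pair"))
  if (!is.numeric(eps) || length(eps) != 1L || eps < 0)
    stop("'eps' must be a single non-negative number")
  cfg <- pair$config
  if (any(dim(pair$bf1) < 4L))
    stop("images must be at least 4 x 4 px to leave a trimmed interior")

  b1 <- pair$bf1 - cfg$dark_level
  b2 <- pair$bf2 - cfg$dark_level
  if (min(b1) < 0 || min(b2) < 0)
    stop("negative intensities after dark subtraction; check 'dark_level'")

  eq <- equalize_pair(defocus_pair(b1, b2, cfg))
  ibar <- (eq$bf1 + eq$bf2) / 2
  fm <- mean(ibar)
  if (!is.finite(fm) || fm <= 0)
    stop("degenerate input: mean intensity is not positive after dark subtraction")
  ibar <- pmax(ibar, 1e-6 * fm)

  src <- (2 * pi * cfg$n_imm / cfg$wavelength_um) *
    (eq$bf1 - eq$bf2) / (ibar * cfg$dz_um)

  t_full <- invert_neg_laplacian(src, cfg$pixel_size_um, eps)
  n <- nrow(t_full); m <- ncol(t_full)
  t_trim <- t_full[2:(n - 1), 2:(m - 1)]
  t_trim <- t_trim - mean(t_trim)
  phase_map(t_trim, cfg$pixel_size_um)
}

#' Background-corrected integrated phase per ROI
#'
#' For each labelled region the integral used for quantification is
#' `A * (mean(T) - mean(T_bkg))` with the area A in physical units
#' (pixel count times pixel area). Subtracting the background mean makes the
#' result invariant under the additive gauge freedom of the TIE solution,
#' and forgiving of loosely drawn contours: background pixels included in a
#' region contribute zero on average.
#'
#' @param phase A [phase_map()].
#' @param rois A [roi_set()] with the same dimensions as `phase$values`.
#' @param labels Optional integer vector restricting which labels to report;
#'   requested labels with no pixels are skipped with a warning.
#' @return A data frame with one row per region: `label`, `n_pixels`,
#'   `area_um2`, `mean_T`, `bkg_T`, `integral_T` (phase times um^2).
#' @export
roi_integrated_phase <- function(phase, rois, labels = NULL) {
  stopifnot(inherits(phase, "phase_map"), inherits(rois, "roi_set"))
  if (!identical(dim(phase$values), dim(rois$labels)))
    stop("ROI label image and phase map must have identical dimensions")
  lab <- rois$labels
  bkg_px <- lab == rois$background_label
  if (!any(bkg_px))
    stop("background region is empty; cannot background-correct integrals")
  bkg_t <- mean(phase$values[bkg_px])

  present <- setdiff(sort(unique(as.vector(lab))), c(0, rois$background_label))
  if (is.null(labels)) {
    labels <- present
  } else {
    missing <- setdiff(labels, present)
    if (length(missing))
      warning("skipping empty ROI label(s): ", paste(missing, collapse = ", "))
    labels <- intersect(labels, present)
  }
  px_area <- phase$pixel_size_um^2
  out <- lapply(labels, function(l) {
    sel <- lab == l
    npx <- sum(sel)
    mt <- mean(phase$values[sel])
    data.frame(label = as.integer(l), n_pixels = npx,
               area_um2 = npx * px_area, mean_T = mt, bkg_T = bkg_t,
               integral_T = npx * px_area * (mt - bkg_t))
  })
  if (!length(out))
    return(data.frame(label = integer(), n_pixels = integer(),
                      area_um2 = numeric(), mean_T = numeric(),
                      bkg_T = numeric(), integral_T = numeric()))
  do.call(rbind, out)
}

# 5-point discrete Laplacian with mirror (edge-replicate) boundary handling,
# in physical units (1/um^2). This is the operator the spectral solver
# inverts exactly at eps = 0.
discrete_laplacian <- function(phi, pixel_size_um) {
  phi <- as_image_matrix(phi, "phi")
  n <- nrow(phi); m <- ncol(phi)
  up    <- phi[c(1, 1:(n - 1)), ]
  down  <- phi[c(2:n, n), ]
  left  <- phi[, c(1, 1:(m - 1))]
  right <- phi[, c(2:m, m)]
  (up + down + left + right - 4 * phi) / pixel_size_um^2
}

# Solve -lap(T) = src for the discrete Laplacian above, by even (mirror)
# extension to a doubled periodic domain and FFT diagonalization. The even
# extension reproduces the edge-replicate boundary condition, so at eps = 0
# this is the exact inverse of discrete_laplacian up to an additive constant.
invert_neg_laplacian <- function(src, pixel_size_um, eps = 0) {
  n <- nrow(src); m <- ncol(src)
  ext <- src[c(1:n, n:1), c(1:m, m:1)]
  fe <- stats::fft(ext)
  kx <- (2 - 2 * cos(2 * pi * (0:(2 * n - 1)) / (2 * n))) / pixel_size_um^2
  ky <- (2 - 2 * cos(2 * pi * (0:(2 * m - 1)) / (2 * m))) / pixel_size_um^2
  k2 <- outer(kx, ky, "+")
  denom <- k2 + eps * max(k2)
  denom[k2 == 0] <- Inf      # DC gauge: undetermined constant set to zero
  te <- fe / denom
  tt <- Re(stats::fft(te, inverse = TRUE)) / (4 * n * m)
  tt[1:n, 1:m]
}
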