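#' Optical acquisition configuration
#'
#' Bundles the acquisition parameters that enter the transport-of-intensity
#' reconstruction: illumination wavelength, the refractive index of the
#' objective's immersion medium, the full axial separation between the two
#' defocused planes, the camera pixel size and the camera dark (bias) level.
#' The refractive index of the mounting medium is recorded for provenance but
#' does not enter the solver: it cancels from the governing equation once the
#' focal-shift correction inside the sample is accounted for.
#'
#' @param wavelength_um Illumination wavelength in vacuum, in micrometres.
#'   Typical TIE acquisition uses a narrow blue band around 0.486 um so that
#'   the dye used for volumetry is transparent.
#' @param n_imm Refractive index of the objective's immersion medium
#'   (1 for dry objectives, about 1.515 for oil immersion). Must be >= 1.
#' @param dz_um Full axial separation between the overfocused and underfocused
#'   planes, in micrometres (e.g. images at +/-0.5 um give `dz_um = 1`).
#' @param pixel_size_um Size of one camera pixel at the sample, in micrometres.
#' @param dark_level Camera dark (bias) counts, subtracted from all images
#'   before any arithmetic. Default 0.
#' @param n_medium Refractive index of the mounting medium (metadata only).
#'
#' @return An object of class `"optical_config"`.
#' @examples
#' cfg <- optical_config(wavelength_um = 0.486, n_imm = 1, dz_um = 1,
#'                       pixel_size_um = 0.3)
#' cfg
#' @export
optical_config <- function(wavelength_um, n_imm = 1, dz_um, pixel_size_um,
                           dark_level = 0, n_medium = 1.337) {
  stopifnot(is.numeric(wavelength_um), length(wavelength_um) == 1L,
            is.numeric(n_imm), is.numeric(dz_um), is.numeric(pixel_size_um),
            is.numeric(dark_level))
  if (wavelength_um <= 0) stop("'wavelength_um' must be positive")
  if (n_imm < 1) stop("'n_imm' must be >= 1")
  if (dz_um <= 0) stop("'dz_um' (full plane separation) must be positive")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be positive")
  if (dark_level < 0) stop("'dark_level' must be >= 0")
  structure(list(wavelength_um = wavelength_um, n_imm = n_imm,
                 dz_um = dz_um, pixel_size_um = pixel_size_um,
                 dark_level = dark_level, n_medium = n_medium),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  wavelength     : %.4g um\n", x$wavelength_um))
  cat(sprintf("  n (immersion)  : %.4g\n", x$n_imm))
  cat(sprintf("  n (medium)     : %.4g  [metadata; cancels from the TIE]\n",
              x$n_medium))
  cat(sprintf("  defocus dz'    : %.4g um (full separation)\n", x$dz_um))
  cat(sprintf("  pixel size     : %.4g um\n", x$pixel_size_um))
  cat(sprintf("  dark level     : %.4g counts\n", x$dark_level))
  invisible(x)
}

#' Defocused brightfield image pair
#'
#' A pair of mutually defocused brightfield transmission images, the raw
#' input of TIE phase retrieval. By convention `bf1` is the overfocused plane
#' and `bf2` the underfocused plane; swapping them flips the sign of the
#' reconstructed phase.
#'
#' @param bf1 Overfocused image, a numeric matrix of intensity counts.
#' @param bf2 Underfocused image, same dimensions as `bf1`.
#' @param config An [optical_config()].
#' @return An object of class `"defocus_pair"`.
#' @export
defocus_pair <- function(bf1, bf2, config) {
  bf1 <- as_image_matrix(bf1, "bf1")
  bf2 <- as_image_matrix(bf2, "bf2")
  if (!identical(dim(bf1), dim(bf2)))
    stop("'bf1' and 'bf2' must have identical dimensions")
  if (!inherits(config, "optical_config"))
    stop("'config' must be an optical_config object")
  structure(list(bf1 = bf1, bf2 = bf2, config = config),
            class = "defocus_pair")
}

#' @export
print.defocus_pair <- function(x, ...) {
  d <- dim(x$bf1)
  cat(sprintf("Defocus pair: %d x %d px, mean counts %.1f / %.1f (over/under)\n",
              d[1], d[2], mean(x$bf1), mean(x$bf2)))
  print(x$config)
  invisible(x)
}

#' Reconstructed phase map
#'
#' The numerical TIE solution T(x, y) in relative phase units. The solver
#' output is gauge-fixed (zero mean) and trimmed by one pixel on every side,
#' so a map reconstructed from an N x M pair is (N-2) x (M-2).
#'
#' @param values Numeric matrix of phase values.
#' @param pixel_size_um Pixel size in micrometres.
#' @return An object of class `"phase_map"`.
#' @export
phase_map <- function(values, pixel_size_um) {
  values <- as_image_matrix(values, "values")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be positive")
  structure(list(values = values, pixel_size_um = pixel_size_um),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Phase map: %d x %d px @ %.3g um/px, range [%.3g, %.3g], mean %.3g\n",
              d[1], d[2], x$pixel_size_um, min(x$values), max(x$values),
              mean(x$values)))
  invisible(x)
}

#' @export
plot.phase_map <- function(x, ...) {
  graphics::image(t(x$values)[, nrow(x$values):1], asp = nrow(x$values) /
                    ncol(x$values), axes = FALSE, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = "TIE phase map (relative units)", ...)
  invisible(x)
}

#' Region-of-interest label set
#'
#' Integer label image addressing cells (or beads) and a designated
#' background region. Label 0 means unassigned; every other label is a
#' region. One label is nominated as background and is used for local
#' baseline correction of both the phase and the dye-exclusion channel.
#'
#' @param labels Integer matrix of region labels (0 = unassigned).
#' @param background_label The label value of the background region.
#' @return An object of class `"roi_set"`.
#' @export
roi_set <- function(labels, background_label) {
  labels <- as_image_matrix(labels, "labels")
  if (any(labels != round(labels)))
    stop("'labels' must contain integer values")
  if (!any(labels == background_label))
    stop("background region is empty: no pixel carries 'background_label'")
  structure(list(labels = labels, background_label = background_label),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$labels))), 0)
  cat(sprintf("ROI set: %d x %d px, %d region(s) (background = %d)\n",
              nrow(x$labels), ncol(x$labels), length(labs),
              x$background_label))
  invisible(x)
}

#' Fixed physical constants of the phase-to-protein conversion
#'
#' The refractive increment of protein solutions (0.185 ml/g, valid for most
#' proteins and nucleic acids, linear up to at least 55% w/v), the partial
#' specific volume coefficient relating protein concentration to water
#' fraction (0.7 ml/g), and the derived ideal-solver phase prefactor
#' 1/(2 pi 0.185) which rounds to 0.86.
#'
#' @return Named list with elements `refractive_increment`,
#'   `specific_volume_coeff` and `phase_prefactor`.
#' @examples
#' physical_constants()$phase_prefactor  # ~0.86
#' @export
physical_constants <- function() {
  list(refractive_increment = 0.185,
       specific_volume_coeff = 0.7,
       phase_prefactor = 1 / (2 * pi * 0.185))
}

# internal: coerce to a plain numeric matrix, preserving dims
as_image_matrix <- function(x, what) {
  if (inherits(x, "phase_map")) x <- x$values
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", what))
  storage.mode(x) <- "double"
  x
}
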