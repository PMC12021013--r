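#' Protein concentration from integrated phase and volume
#'
#' The core quantity of the workflow: P = s * (integrated phase) / V, with s
#' the calibrated (or ideal, [theoretical_s()]) conversion coefficient in
#' um, integrated phase in phase um^2 and volume in um^3, giving P in g/ml.
#' Assumes the protein concentration of the surrounding medium is
#' negligible; otherwise the result is the excess concentration over the
#' medium.
#'
#' @param integrated_phase Background-corrected integrated phase (phase um^2).
#' @param volume_um3 Cell volume in um^3 (> 0).
#' @param s Conversion coefficient in um (> 0).
#' @return Protein concentration in g/ml.
#' @export
protein_concentration <- function(integrated_phase, volume_um3, s) {
  if (any(volume_um3 <= 0)) stop("'volume_um3' must be positive")
  if (any(s <= 0)) stop("'s' must be positive")
  s * integrated_phase / volume_um3
}

#' Water content from protein concentration
#'
#' The fraction of cell volume occupied by water relates to protein
#' concentration through the partial specific volume of protein:
#' W = 1 - 0.7 P. Values of P outside [0, 1/0.7] g/ml put W outside [0, 1];
#' such values are reported unclamped (attribute `out_of_range` flags them).
#'
#' @param P Protein concentration in g/ml (>= 0, vectorized).
#' @return Water volume fraction (dimensionless).
#' @export
water_content <- function(P) {
  if (any(P < 0)) stop("'P' must be >= 0")
  w <- 1 - physical_constants()$specific_volume_coeff * P
  if (any(w < 0 | w > 1)) attr(w, "out_of_range") <- which(w < 0 | w > 1)
  w
}

#' Refractive index elevation from protein concentration
#'
#' Protein solutions raise the refractive index over the solvent linearly,
#' Delta n = 0.185 P, with the 0.185 ml/g refractive increment valid for
#' most proteins and nucleic acids up to at least 55% w/v.
#'
#' @param P Protein concentration in g/ml (>= 0, vectorized).
#' @return Refractive index elevation over the solvent (dimensionless).
#' @export
refractive_index_increment <- function(P) {
  if (any(P < 0)) stop("'P' must be >= 0")
  physical_constants()$refractive_increment * P
}

#' Dry mass from integrated phase
#'
#' The product of volume and protein concentration is the total protein
#' (dry) mass, which depends only on the integrated phase:
#' m = (lambda / (2 pi 0.185)) * integrated phase. With phase in um^2 and
#' lambda in um the result is in pg (1 g/ml = 1 pg/um^3). Equals
#' `protein_concentration(...) * V` when the same s is used.
#'
#' @param integrated_phase Background-corrected integrated phase (phase um^2).
#' @param wavelength_um Vacuum wavelength in micrometres (> 0).
#' @return Dry mass in picograms.
#' @export
dry_mass <- function(integrated_phase, wavelength_um) {
  if (any(wavelength_um <= 0)) stop("'wavelength_um' must be positive")
  theoretical_s(wavelength_um) * integrated_phase
}

#' Per-cell protein concentration, water content and dry mass
#'
#' Fuses the two measurement channels on a shared ROI label image: the
#' background-corrected integrated phase of each region (TIE channel) and
#' its dye-exclusion volume (TTD channel) combine into protein
#' concentration P = s Sum(T)/V, water fraction W = 1 - 0.7 P, refractive
#' index elevation 0.185 P, and dry mass P V in pg. The phase map is 2 px
#' smaller than the raw images, so `rois_phase` (matching the phase map) may
#' be supplied separately from `rois` (matching the TTD image); by default
#' the TTD label image is centre-cropped by 1 px per side to match.
#'
#' @param phase A [phase_map()] from [solve_tie()].
#' @param ttd A [ttd_image()].
#' @param rois A [roi_set()] matching the TTD image.
#' @param s Conversion coefficient in um: a number, a
#'   `bead_calibration` object, or `NULL` to use
#'   `theoretical_s(wavelength_um)`.
#' @param dye A [dye_solution()] with `alpha_per_um` set.
#' @param wavelength_um Needed only when `s` is `NULL`.
#' @param rois_phase Optional [roi_set()] matching the phase map dimensions.
#' @return An object of class `"cell_quantification"`: a data frame with one
#'   row per region (`roi_label`, `area_um2`, `volume_um3`, `integral_T`,
#'   `P_g_per_ml`, `W`, `delta_n`, `dry_mass_pg`).
#' @export
quantify_cells <- function(phase, ttd, rois, s = NULL, dye,
                           wavelength_um = NULL, rois_phase = NULL) {
  stopifnot(inherits(phase, "phase_map"), inherits(ttd, "ttd_image"),
            inherits(rois, "roi_set"))
  if (inherits(s, "bead_calibration")) s <- s$s
  if (is.null(s)) {
    if (is.null(wavelength_um))
      stop("supply either 's' or 'wavelength_um'")
    s <- theoretical_s(wavelength_um)
  }
  if (is.null(rois_phase)) {
    lab <- rois$labels
    n <- nrow(lab); m <- ncol(lab)
    if (!identical(dim(phase$values), c(n - 2L, m - 2L)))
      stop("phase map is not the 1-px-trimmed version of the ROI image; ",
           "pass 'rois_phase' explicitly")
    rois_phase <- roi_set(lab[2:(n - 1), 2:(m - 1)], rois$background_label)
  }
  ph <- roi_integrated_phase(phase, rois_phase)
  vol <- roi_volume(ttd, rois, dye)
  merged <- merge(ph[, c("label", "integral_T")],
                  vol[, c("label", "area_um2", "volume_um3")], by = "label")
  if (!nrow(merged))
    warning("no region present in both channels")
  bad <- merged$volume_um3 <= 0
  if (any(bad)) {
    warning("dropping region(s) with non-positive volume: ",
            paste(merged$label[bad], collapse = ", "))
    merged <- merged[!bad, , drop = FALSE]
  }
  P <- protein_concentration(merged$integral_T, merged$volume_um3, s)
  out <- data.frame(roi_label = merged$label,
                    area_um2 = merged$area_um2,
                    volume_um3 = merged$volume_um3,
                    integral_T = merged$integral_T,
                    P_g_per_ml = P,
                    W = as.numeric(water_content(pmax(P, 0))),
                    delta_n = physical_constants()$refractive_increment * P,
                    dry_mass_pg = P * merged$volume_um3)
  attr(out, "s_um") <- s
  class(out) <- c("cell_quantification", "data.frame")
  out
}

#' @export
print.cell_quantification <- function(x, ...) {
  cat(sprintf("Per-cell quantification (%d region(s), s = %.4g um)\n",
              nrow(x), attr(x, "s_um")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
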