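#' Dye solution used for transmission-through-dye volumetry
#'
#' Describes the strongly absorbing, membrane-impermeant extracellular dye
#' (typically Acid Blue 9 / Brilliant Blue FCF, absorbance peak 630 nm) that
#' provides the thickness contrast: cells exclude the dye, so thicker cells
#' transmit more light.
#'
#' @param alpha_per_um Absorption coefficient of the solution in 1/um at the
#'   imaging wavelength; for 7 mg/ml AB9 a typical value is 0.15-0.16.
#'   Measure it per batch with [fit_absorption()].
#' @param concentration_mg_ml Dye concentration in mg/ml (metadata; used by
#'   the osmolality helper).
#' @return An object of class `"dye_solution"`.
#' @export
dye_solution <- function(alpha_per_um = NA_real_, concentration_mg_ml = NA_real_) {
  if (!is.na(alpha_per_um) && alpha_per_um <= 0)
    stop("'alpha_per_um' must be positive when set")
  if (!is.na(concentration_mg_ml) && concentration_mg_ml < 0)
    stop("'concentration_mg_ml' must be >= 0")
  structure(list(alpha_per_um = alpha_per_um,
                 concentration_mg_ml = concentration_mg_ml,
                 osmolality_slope = 2.25),
            class = "dye_solution")
}

#' @export
print.dye_solution <- function(x, ...) {
  cat(sprintf("Dye solution: alpha = %s /um, C = %s mg/ml\n",
              format(x$alpha_per_um), format(x$concentration_mg_ml)))
  invisible(x)
}

#' Transmission-through-dye image
#'
#' A transmission image taken at the dye's absorbance peak. The background
#' (cell-free, full dye depth) log-intensity may be supplied directly or
#' computed later from a background ROI with [ttd_background()].
#'
#' @param intensity Numeric matrix of intensity counts.
#' @param pixel_size_um Pixel size in micrometres.
#' @param dark_level Camera dark counts to subtract before taking logarithms.
#' @param background_log_intensity Mean natural-log intensity of the
#'   background region (dark-subtracted), if already known.
#' @return An object of class `"ttd_image"`.
#' @export
ttd_image <- function(intensity, pixel_size_um, dark_level = 0,
                      background_log_intensity = NA_real_) {
  intensity <- as_image_matrix(intensity, "intensity")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be positive")
  if (dark_level < 0) stop("'dark_level' must be >= 0")
  structure(list(intensity = intensity, pixel_size_um = pixel_size_um,
                 dark_level = dark_level,
                 background_log_intensity = background_log_intensity),
            class = "ttd_image")
}

#' @export
print.ttd_image <- function(x, ...) {
  cat(sprintf("TTD image: %d x %d px @ %.3g um/px, counts [%.4g, %.4g], ln(I_bkg) = %s\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size_um,
              min(x$intensity), max(x$intensity),
              format(x$background_log_intensity)))
  invisible(x)
}

# dark-subtracted intensities for quantification; dark pixels are an error
# (they indicate saturation or a misconfigured dark level), not a clamp.
ttd_counts <- function(img) {
  v <- img$intensity - img$dark_level
  if (any(v <= 0)) {
    bad <- which(v <= 0)[1]
    stop(sprintf(paste0("non-positive intensity after dark subtraction ",
                        "(first offending pixel value %.6g at index %d); ",
                        "check 'dark_level' and exposure"),
                 v[bad], bad))
  }
  v
}

#' Mean log background intensity of a TTD image
#'
#' Computes the mean of the natural-log, dark-subtracted intensity over the
#' background region (the mean of logs, matching the protocol of measuring
#' the average logarithmic intensity) and stores it on the image.
#'
#' @param img A [ttd_image()].
#' @param rois A [roi_set()] matching the image dimensions.
#' @return The image with `background_log_intensity` filled in.
#' @export
ttd_background <- function(img, rois) {
  stopifnot(inherits(img, "ttd_image"), inherits(rois, "roi_set"))
  if (!identical(dim(img$intensity), dim(rois$labels)))
    stop("ROI label image and TTD image must have identical dimensions")
  v <- ttd_counts(img)
  img$background_log_intensity <-
    mean(log(v[rois$labels == rois$background_label]))
  img
}

#' Thickness map from a dye-exclusion image
#'
#' Inverts the Beer-Lambert law pixel by pixel:
#' \deqn{h(x,y) = \frac{\ln I(x,y) - \ln I_{bkg}}{\alpha}.}
#' Cells exclude the dye, appear brighter than the background, and so map to
#' positive thickness. The result is invariant under any joint rescaling of
#' the image and the background intensity (exposure invariance).
#'
#' @param img A [ttd_image()] with `background_log_intensity` set (see
#'   [ttd_background()]).
#' @param dye A [dye_solution()] with `alpha_per_um` set.
#' @return A list of class `"height_map"` with `values` (um) and
#'   `pixel_size_um`.
#' @export
height_map <- function(img, dye) {
  stopifnot(inherits(img, "ttd_image"), inherits(dye, "dye_solution"))
  if (is.na(dye$alpha_per_um)) stop("dye absorption coefficient is not set")
  if (is.na(img$background_log_intensity))
    stop("background log intensity is not set; call ttd_background() first")
  v <- ttd_counts(img)
  h <- (log(v) - img$background_log_intensity) / dye$alpha_per_um
  structure(list(values = h, pixel_size_um = img$pixel_size_um),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("Height map: %d x %d px @ %.3g um/px, h in [%.3g, %.3g] um\n",
              nrow(x$values), ncol(x$values), x$pixel_size_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Cell volume per ROI from a dye-exclusion image
#'
#' Integrates the Beer-Lambert thickness over each labelled region:
#' \deqn{V = \frac{A}{\alpha}\,(\overline{\ln I} - \overline{\ln I_{bkg}}),}
#' with the area A in um^2 and the background taken as the mean log
#' intensity over the background region. With `local_background_margin`
#' finite, each region uses only background pixels within that margin (in
#' pixels) of its bounding box, which compensates slow illumination
#' gradients; the default uses the whole background region.
#'
#' @param img A [ttd_image()].
#' @param rois A [roi_set()] matching the image.
#' @param dye A [dye_solution()] with `alpha_per_um` set.
#' @param labels Optional restriction of labels, as in
#'   [roi_integrated_phase()].
#' @param local_background_margin Margin in pixels around each ROI bounding
#'   box for local background selection; `Inf` (default) = global.
#' @return Data frame per region: `label`, `n_pixels`, `area_um2`,
#'   `mean_lnI`, `bkg_lnI`, `volume_um3`.
#' @export
roi_volume <- function(img, rois, dye, labels = NULL,
                       local_background_margin = Inf) {
  stopifnot(inherits(img, "ttd_image"), inherits(rois, "roi_set"),
            inherits(dye, "dye_solution"))
  if (is.na(dye$alpha_per_um)) stop("dye absorption coefficient is not set")
  if (!identical(dim(img$intensity), dim(rois$labels)))
    stop("ROI label image and TTD image must have identical dimensions")
  lnv <- log(ttd_counts(img))
  lab <- rois$labels
  bkg_px <- lab == rois$background_label
  if (!any(bkg_px)) stop("background region is empty")

  present <- setdiff(sort(unique(as.vector(lab))), c(0, rois$background_label))
  if (is.null(labels)) {
    labels <- present
  } else {
    missing <- setdiff(labels, present)
    if (length(missing))
      warning("skipping empty ROI label(s): ", paste(missing, collapse = ", "))
    labels <- intersect(labels, present)
  }
  px_area <- img$pixel_size_um^2
  global_bkg <- mean(lnv[bkg_px])
  out <- lapply(labels, function(l) {
    sel <- lab == l
    npx <- sum(sel)
    if (is.finite(local_background_margin)) {
      ij <- which(sel, arr.ind = TRUE)
      r0 <- max(1, min(ij[, 1]) - local_background_margin)
      r1 <- min(nrow(lab), max(ij[, 1]) + local_background_margin)
      c0 <- max(1, min(ij[, 2]) - local_background_margin)
      c1 <- min(ncol(lab), max(ij[, 2]) + local_background_margin)
      win <- matrix(FALSE, nrow(lab), ncol(lab))
      win[r0:r1, c0:c1] <- TRUE
      loc <- bkg_px & win
      bkg_ln <- if (any(loc)) mean(lnv[loc]) else global_bkg
    } else {
      bkg_ln <- global_bkg
    }
    mln <- mean(lnv[sel])
    data.frame(label = as.integer(l), n_pixels = npx,
               area_um2 = npx * px_area, mean_lnI = mln, bkg_lnI = bkg_ln,
               volume_um3 = npx * px_area * (mln - bkg_ln) / dye$alpha_per_um)
  })
  if (!length(out))
    return(data.frame(label = integer(), n_pixels = integer(),
                      area_um2 = numeric(), mean_lnI = numeric(),
                      bkg_lnI = numeric(), volume_um3 = numeric()))
  do.call(rbind, out)
}

#' Rule-of-thumb maximum dye concentration for a chamber depth
#'
#' The background (full dye depth) must stay well above the camera dark
#' level, which bounds the usable dye concentration by C <= 300 / h' with
#' h' the coverslip-to-slide distance in um. A 40-um spacer thus allows up
#' to 7.5 mg/ml; the commonly used 7 mg/ml satisfies the bound.
#'
#' @param chamber_depth_um Chamber depth h' in micrometres (> 0).
#' @return Maximum recommended concentration in mg/ml.
#' @export
recommended_max_concentration <- function(chamber_depth_um) {
  if (any(chamber_depth_um <= 0))
    stop("'chamber_depth_um' must be positive")
  300 / chamber_depth_um
}

#' Osmolality added by the dye
#'
#' Dissolved Acid Blue 9 raises the osmolality of the medium approximately
#' linearly over 0-100 mg/ml, by 2.25 mosm/kg per mg/ml. Relevant mainly at
#' the high concentrations (~80 mg/ml) needed for bacteria.
#'
#' @param concentration_mg_ml Dye concentration in mg/ml (>= 0).
#' @return Added osmolality in mosm/kg.
#' @export
dye_osmolality <- function(concentration_mg_ml) {
  if (any(concentration_mg_ml < 0))
    stop("'concentration_mg_ml' must be >= 0")
  2.25 * concentration_mg_ml
}
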