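#' Batch TTD/TIE processing of image triplets
#'
#' Automates multi-ROI processing of acquisitions stored as file triplets
#' named `[name]bf1.tif` (overfocused), `[name]bf2.tif` (underfocused) and
#' `[name]ttd.tif` (dye-exclusion image), all pre-aligned and sharing one
#' ROI label image. Each region is cropped to its bounding box (plus a
#' margin so that local background is available), the phase is reconstructed
#' on the crop, the volume integrated from the TTD crop, and the per-cell
#' quantities assembled into one CSV. The cropped TTD image and the cropped
#' underfocused brightfield image are written per region as
#' `ROI_<label>_TTD_TIE_<name>_ttd.tif` / `..._bf2.tif`. Processing
#' continues past per-ROI and per-triplet failures, which are logged to
#' stderr.
#'
#' @param dir Directory holding the image triplets.
#' @param rois A [roi_set()] (or path to a label image) matching the raw
#'   image dimensions.
#' @param config An [optical_config()] (or path to a config file, see
#'   [load_run_config()]).
#' @param dye A [dye_solution()] with `alpha_per_um` set (taken from the
#'   config file when one is given).
#' @param s Conversion coefficient in um, a `bead_calibration`, or `NULL`
#'   for the ideal-solver value at the configured wavelength.
#' @param out_dir Output directory (created if needed).
#' @param eps Damping passed to [solve_tie()].
#' @param margin_px Crop margin around each ROI bounding box (default 8).
#' @param background_label Used only when `rois` is a path.
#' @return Invisibly, a list with `results` (the combined data frame, also
#'   written to `out_dir/results.csv`), `n_processed` and `n_failed`
#'   (non-zero when any triplet or ROI was skipped).
#' @export
batch_process <- function(dir, rois, config, dye = NULL, s = NULL,
                          out_dir = file.path(dir, "out"), eps = 1e-3,
                          margin_px = 8L, background_label = NULL) {
  if (is.character(config)) {
    rc <- load_run_config(config)
    config <- rc$optical
    if (is.null(dye)) dye <- rc$dye
  }
  stopifnot(inherits(config, "optical_config"))
  if (is.null(dye) || is.na(dye$alpha_per_um))
    stop("a dye_solution with 'alpha_per_um' set is required")
  if (is.character(rois)) {
    if (is.null(background_label))
      stop("'background_label' is required when 'rois' is a path")
    rois <- load_roi_labels(rois, background_label)
  }
  stopifnot(inherits(rois, "roi_set"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  bf1_files <- list.files(dir, pattern = "bf1\\.(tif|tiff)$",
                          ignore.case = TRUE)
  if (!length(bf1_files))
    log_msg("WARN", "no '[name]bf1' TIFF files found in ", dir)
  rows <- list()
  n_failed <- 0L
  labs <- setdiff(sort(unique(as.vector(rois$labels))),
                  c(0, rois$background_label))
  if (!length(labs)) log_msg("WARN", "ROI set contains no regions; no-op")

  for (f1 in bf1_files) {
    base <- sub("bf1\\.(tif|tiff)$", "", f1, ignore.case = TRUE)
    ext <- sub(".*bf1\\.", "", f1, ignore.case = TRUE)
    f2 <- file.path(dir, paste0(base, "bf2.", ext))
    ft <- file.path(dir, paste0(base, "ttd.", ext))
    if (!file.exists(f2) || !file.exists(ft)) {
      log_msg("ERROR", "incomplete triplet for '", base, "': missing ",
              paste(basename(c(f2, ft))[!file.exists(c(f2, ft))],
                    collapse = ", "), "; skipped")
      n_failed <- n_failed + 1L
      next
    }
    ok <- tryCatch({
      bf1 <- load_image(file.path(dir, f1))
      bf2 <- load_image(f2)
      ttd_raw <- load_image(ft)
      if (!identical(dim(bf1), dim(bf2)) ||
          !identical(dim(bf1), dim(ttd_raw)))
        stop("triplet images have mismatched dimensions")
      if (!identical(dim(bf1), dim(rois$labels)))
        stop("ROI label image does not match the image dimensions")
      TRUE
    }, error = function(e) {
      log_msg("ERROR", "triplet '", base, "' skipped: ",
              conditionMessage(e))
      FALSE
    })
    if (!ok) { n_failed <- n_failed + 1L; next }

    for (l in labs) {
      res <- tryCatch({
        sel <- which(rois$labels == l, arr.ind = TRUE)
        r0 <- max(1L, min(sel[, 1]) - margin_px)
        r1 <- min(nrow(bf1), max(sel[, 1]) + margin_px)
        c0 <- max(1L, min(sel[, 2]) - margin_px)
        c1 <- min(ncol(bf1), max(sel[, 2]) + margin_px)
        lab_crop <- rois$labels[r0:r1, c0:c1]
        lab_crop[!(lab_crop %in% c(l, rois$background_label))] <- 0
        rois_crop <- roi_set(lab_crop, rois$background_label)
        pair <- defocus_pair(bf1[r0:r1, c0:c1], bf2[r0:r1, c0:c1], config)
        tmap <- solve_tie(pair, eps = eps)
        ttd_crop <- ttd_image(ttd_raw[r0:r1, c0:c1], config$pixel_size_um,
                              dark_level = config$dark_level)
        q <- quantify_cells(tmap, ttd_crop, rois_crop, s = s, dye = dye,
                            wavelength_um = config$wavelength_um)
        q <- q[q$roi_label == l, , drop = FALSE]
        if (!nrow(q)) stop("region ", l, " lost in crop")
        write_float_tiff(ttd_crop$intensity,
                         file.path(out_dir,
                                   sprintf("ROI_%d_TTD_TIE_%sttd.tif", l, base)))
        write_float_tiff(pair$bf2,
                         file.path(out_dir,
                                   sprintf("ROI_%d_TTD_TIE_%sbf2.tif", l, base)))
        cbind(source = base, q)
      }, error = function(e) {
        log_msg("ERROR", "ROI ", l, " of '", base, "' skipped: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) n_failed <- n_failed + 1L else
        rows[[length(rows) + 1L]] <- res
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), roi_label = integer(),
               area_um2 = numeric(), volume_um3 = numeric(),
               integral_T = numeric(), P_g_per_ml = numeric(),
               W = numeric(), delta_n = numeric(), dry_mass_pg = numeric())
  write_quant_csv(results, file.path(out_dir, "results.csv"))
  log_msg("INFO", nrow(results), " region measurement(s) written to ",
          file.path(out_dir, "results.csv"),
          if (n_failed) paste0(" (", n_failed, " failure(s))") else "")
  invisible(list(results = results, n_processed = nrow(results),
                 n_failed = n_failed))
}
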