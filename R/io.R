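#' Load a single-page grayscale image
#'
#' Reads an 8/16-bit integer or 32-bit float single-page grayscale TIFF into
#' a plain numeric matrix of counts. Integer images are returned as raw
#' counts (no rescaling to [0, 1]); float images are returned as stored.
#'
#' @param path Path to a TIFF file.
#' @return Numeric matrix; attribute `bits_per_sample` when known.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 1L)
    stop("multi-page TIFF not supported: ", path,
         " (split the stack into individual images first)")
  img <- tryCatch(suppressWarnings(tiff::readTIFF(path, as.is = TRUE)),
                  error = function(e) pages[[1]])
  if (length(dim(img)) == 3L)
    stop("RGB/multi-channel TIFF not supported: ", path,
         " (convert to single-channel grayscale first)")
  storage.mode(img) <- "double"
  img
}

#' Write a matrix as a 32-bit float grayscale TIFF
#'
#' Uncompressed single-strip little-endian TIFF with IEEE float samples,
#' preserving arbitrary (including negative) values exactly at float32
#' precision. This is the lossless output format for phase maps and
#' synthetic count images.
#'
#' @param mat Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(mat, path) {
  mat <- as_image_matrix(mat, "mat")
  n <- nrow(mat); m <- ncol(mat)
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  # header: byte order II, magic 42, IFD offset after the pixel data
  writeBin(charToRaw("II"), con)
  w2(42L)
  nbytes <- 4L * n * m
  w4(8L + nbytes)
  # pixel data, row-major float32
  writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  # IFD: entry = tag, type, count, value (SHORT values left-justified)
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  w2(10L)                                  # entry count
  entry(256L, 3L, 1L, m)                   # ImageWidth
  entry(257L, 3L, 1L, n)                   # ImageLength
  entry(258L, 3L, 1L, 32L)                 # BitsPerSample
  entry(259L, 3L, 1L, 1L)                  # Compression: none
  entry(262L, 3L, 1L, 1L)                  # Photometric: BlackIsZero
  entry(273L, 4L, 1L, 8L)                  # StripOffsets
  entry(277L, 3L, 1L, 1L)                  # SamplesPerPixel
  entry(278L, 3L, 1L, n)                   # RowsPerStrip
  entry(279L, 4L, 1L, nbytes)              # StripByteCounts
  entry(339L, 3L, 1L, 3L)                  # SampleFormat: IEEE float
  w4(0L)                                   # no next IFD
  invisible(path)
}

#' Write a matrix as a 16-bit integer grayscale TIFF
#'
#' Counts are rounded and must fit in 0..65535.
#'
#' @param mat Numeric matrix of counts.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_uint16_tiff <- function(mat, path) {
  mat <- round(as_image_matrix(mat, "mat"))
  if (min(mat) < 0 || max(mat) > 65535)
    stop("counts outside the 16-bit range 0..65535")
  tiff::writeTIFF(mat / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Load a ROI label image
#'
#' Reads an integer label image (TIFF or PNG) into a [roi_set()]. PNG pixel
#' values are mapped back to integer labels using the file's bit depth.
#'
#' @param path Path to a label TIFF/PNG (0 = unassigned).
#' @param background_label Label value of the background region.
#' @return A [roi_set()].
#' @export
load_roi_labels <- function(path, background_label) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    lab <- load_image(path)
  } else if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    if (length(dim(raw)) == 3L)
      stop("RGB label PNG not supported; use a single-channel image")
    depth <- attr(raw, "info")$bit.depth
    if (is.null(depth)) depth <- 8
    lab <- round(raw * (2^depth - 1))
    attributes(lab) <- list(dim = dim(lab))
  } else {
    stop("unsupported label format: ", ext)
  }
  roi_set(round(lab), background_label)
}

#' Load an acquisition configuration file
#'
#' Reads a JSON or YAML configuration with keys `wavelength_um`, `n_imm`,
#' `dz_um`, `pixel_size_um` and optional `dark_level`, `n_medium`,
#' `alpha_per_um`, `dye_concentration_mg_ml`, and validates the units on
#' load.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return List with elements `optical` ([optical_config()]) and `dye`
#'   ([dye_solution()]).
#' @export
load_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                json = jsonlite::fromJSON(path),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("unsupported config format: ", ext))
  need <- c("wavelength_um", "n_imm", "dz_um", "pixel_size_um")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config is missing required key(s): ", paste(miss, collapse = ", "))
  optical <- optical_config(
    wavelength_um = cfg$wavelength_um, n_imm = cfg$n_imm,
    dz_um = cfg$dz_um, pixel_size_um = cfg$pixel_size_um,
    dark_level = if (is.null(cfg$dark_level)) 0 else cfg$dark_level,
    n_medium = if (is.null(cfg$n_medium)) 1.337 else cfg$n_medium)
  dye <- dye_solution(
    alpha_per_um = if (is.null(cfg$alpha_per_um)) NA_real_ else cfg$alpha_per_um,
    concentration_mg_ml = if (is.null(cfg$dye_concentration_mg_ml))
      NA_real_ else cfg$dye_concentration_mg_ml)
  list(optical = optical, dye = dye)
}

#' Write a calibration result to JSON
#'
#' @param fit A `bead_calibration` or `absorption_fit` object.
#' @param path Output path.
#' @param wavelength_um Optional wavelength recorded alongside a bead fit.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(fit, path, wavelength_um = NA_real_) {
  out <- if (inherits(fit, "bead_calibration")) {
    list(k = fit$k, g = fit$g, s_um = fit$s, r2 = fit$r_squared,
         n_bead = fit$n_bead, v_bead_um3 = fit$v_bead_um3,
         lambda_um = wavelength_um)
  } else if (inherits(fit, "absorption_fit")) {
    list(alpha_per_um = fit$alpha_per_um, r2 = fit$r_squared,
         n_points = fit$n_points)
  } else stop("unsupported calibration object")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a per-ROI results table as CSV
#'
#' Numeric columns are formatted with a fixed 10-significant-digit format so
#' that identical inputs produce byte-identical files.
#'
#' @param df Data frame of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.10g", col) else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# timestamped log line on stderr; results never go to stderr
log_msg <- function(level, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(...)))
}
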