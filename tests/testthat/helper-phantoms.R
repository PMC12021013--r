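# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except in the explicit I/O tests.

default_config <- function(dz_um = 0.1, pixel_size_um = 0.3, dark_level = 0,
                           n_medium = 1.337) {
  optical_config(wavelength_um = 0.486, n_imm = 1, dz_um = dz_um,
                 pixel_size_um = pixel_size_um, dark_level = dark_level,
                 n_medium = n_medium)
}

# disk label image: label 1 = disk of given radius (um) about the centre,
# label 2 = background everywhere else
disk_rois <- function(shape, radius_um, pixel_size_um = 0.3,
                      center = (shape + 1) / 2) {
  rho <- sqrt(outer(((seq_len(shape[1]) - center[1]) * pixel_size_um)^2,
                    ((seq_len(shape[2]) - center[2]) * pixel_size_um)^2,
                    "+"))
  lab <- matrix(2L, shape[1], shape[2])
  lab[rho < radius_um] <- 1L
  roi_set(lab, background_label = 2L)
}

# centre-crop a roi_set by 1 px per side, to match a solver output
trim_rois <- function(rois) {
  n <- nrow(rois$labels); m <- ncol(rois$labels)
  roi_set(rois$labels[2:(n - 1), 2:(m - 1)], rois$background_label)
}

# matrix with an exactly prescribed mean
matrix_with_mean <- function(target_mean, n, m, seed = 1) {
  x <- with_seed_test(seed, matrix(stats::runif(n * m, 900, 1100), n, m))
  x - mean(x) + target_mean
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# full synthetic bead-in-oil calibration run: render defocus pairs for each
# oil, reconstruct, integrate, fit. Returns the bead_calibration.
run_synthetic_bead_calibration <- function(n_oils, n_bead = 1.43,
                                           diameter_um = 7.7, eps = 0,
                                           shape = c(128L, 128L)) {
  cfg <- default_config()
  rois <- trim_rois(disk_rois(shape, diameter_um / 2 + 1.5))
  obs <- do.call(rbind, lapply(n_oils, function(no) {
    bp <- bead_phase_map(diameter_um, n_bead - no, cfg$wavelength_um,
                         cfg$pixel_size_um, shape)
    tm <- solve_tie(forward_tie_pair(bp, 1000, cfg), eps = eps)
    ip <- roi_integrated_phase(tm, rois)
    data.frame(n_oil = no, t_bead = ip$integral_T, n_beads = 1L)
  }))
  fit_bead_calibration(obs, v_bead_um3 = sphere_volume(diameter_um),
                       n_bead = n_bead)
}

# render one dome-shaped cell at protein concentration P0 (g/ml) into a
# defocus pair + TTD image, run the full pipeline, return the quantification.
# dz = 0.5 um: the largest defocus step the steep-edged cap admits in the
# geometric forward model (contrast stays below 1 up to P0 = 0.3), giving a
# realistic defocus signal relative to camera noise
quantify_synthetic_cell <- function(P0, alpha = 0.15, shape = c(128L, 128L),
                                    base_radius_um = 9, height_um = 6,
                                    eps = 0, noise = NULL, seed = NULL) {
  cfg <- default_config(dz_um = 0.5)
  cap <- cap_cell_height(base_radius_um, height_um, cfg$pixel_size_um, shape)
  dn <- refractive_index_increment(P0)
  phi <- phase_map(2 * pi / cfg$wavelength_um * dn * cap$values,
                   cfg$pixel_size_um)
  pair <- forward_tie_pair(phi, 1000, cfg, noise = noise, seed = seed)
  tmap <- solve_tie(pair, eps = eps)
  ttd <- ttd_image_from_height(cap, alpha, 2000, noise = noise,
                               seed = if (is.null(seed)) NULL else seed + 7L)
  rois <- disk_rois(shape, base_radius_um + 1.2)
  quantify_cells(tmap, ttd, rois, s = NULL, dye = dye_solution(alpha),
                 wavelength_um = cfg$wavelength_um)
}
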