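# Synthetic microcrystal wedge simulator.
#
# The simulator reproduces the statistical structure that the assembly
# pipeline consumes, not the physics of diffraction: every observable
# symmetry image of every unique reflection is assigned a uniform random
# diffraction angle on [0, 360); a crystal records the images falling
# inside its wedge, on a frame chosen by angle bin.  Recorded intensities
# follow a Wilson (exponential) reference set modulated by a per-crystal
# multiplicative scale k and isotropic B falloff, with Gaussian noise of
# variance (I + noise_floor).  A configurable minority of crystals are
# non-isomorphous outliers: their intensities are drawn from a second set
# correlated rho with the truth and their cells carry a systematic shift.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-wedge generator.  Defaults mirror
#' the acquisition this package models: many ~20 degree rotation wedges,
#' one per microcrystal, in an orthorhombic P212121 cell.
#'
#' @param n_crystals number of partial datasets.
#' @param cell0 reference [unit_cell()].
#' @param cell_jitter_sigma normal jitter (Angstrom) on cell lengths;
#'   `angle_jitter_sigma` (degrees) on angles.
#' @param angle_jitter_sigma see above.
#' @param sg a [space_group()] or built-in symbol.
#' @param d_min high-resolution limit in Angstrom.
#' @param wilson_Sigma0 mean intensity at zero scattering angle.
#' @param wilson_B Wilson B (A^2) of the reference intensity falloff.
#' @param scale_range range `(k_min, k_max)` of per-crystal scales.
#' @param B_range range (A^2) of per-crystal isotropic B offsets.
#' @param wedge_width rotation range per crystal in degrees (default 20).
#' @param frames_per_wedge frames the wedge is divided into.
#' @param noise_floor background variance added to the Poisson-like term.
#' @param noise_scale multiplier on the noise standard deviation (1 =
#'   nominal; 0 = noiseless limit for identity tests).
#' @param n_outliers number of non-isomorphous crystals (< n_crystals).
#' @param outlier_corr correlation rho of outlier intensities with truth.
#' @param outlier_cell_shift systematic shift (Angstrom) added to the `a`
#'   axis of outlier crystals.
#' @param anom_fraction |Delta I| / I scale of the simulated anomalous
#'   signal (0 = none).
#' @param wavelength in Angstrom.
#' @param seed integer; fixing it makes the full collection bytewise
#'   reproducible.
#' @return validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_crystals = 132,
                              cell0 = unit_cell(40, 50, 60),
                              cell_jitter_sigma = 0.05,
                              angle_jitter_sigma = 0.02,
                              sg = "P212121",
                              d_min = 3,
                              wilson_Sigma0 = 100,
                              wilson_B = 20,
                              scale_range = c(0.5, 2),
                              B_range = c(0, 20),
                              wedge_width = 20,
                              frames_per_wedge = 10,
                              noise_floor = 25,
                              noise_scale = 1,
                              n_outliers = 0,
                              outlier_corr = 0.5,
                              outlier_cell_shift = 0.5,
                              anom_fraction = 0,
                              wavelength = 0.979,
                              seed = 1) {
  cfg <- list(n_crystals = as.integer(n_crystals),
              cell0 = as_unit_cell(cell0),
              cell_jitter_sigma = cell_jitter_sigma,
              angle_jitter_sigma = angle_jitter_sigma,
              sg = as_space_group(sg),
              d_min = d_min,
              wilson_Sigma0 = wilson_Sigma0,
              wilson_B = wilson_B,
              scale_range = scale_range,
              B_range = B_range,
              wedge_width = wedge_width,
              frames_per_wedge = as.integer(frames_per_wedge),
              noise_floor = noise_floor,
              noise_scale = noise_scale,
              n_outliers = as.integer(n_outliers),
              outlier_corr = outlier_corr,
              outlier_cell_shift = outlier_cell_shift,
              anom_fraction = anom_fraction,
              wavelength = wavelength,
              seed = as.integer(seed))
  if (cfg$n_crystals < 1) stop("n_crystals must be >= 1")
  if (cfg$n_outliers >= cfg$n_crystals)
    stop("n_outliers must be smaller than n_crystals")
  if (cfg$outlier_corr < 0 || cfg$outlier_corr > 1)
    stop("outlier_corr must lie in [0, 1]")
  if (cfg$d_min <= 0) stop("d_min must be positive")
  if (!(cfg$wedge_width > 0 && cfg$wedge_width <= 360))
    stop("wedge_width must lie in (0, 360]")
  if (cfg$frames_per_wedge < 1) stop("frames_per_wedge must be >= 1")
  if (cfg$noise_floor < 0 || cfg$noise_scale < 0)
    stop("noise parameters must be non-negative")
  structure(cfg, class = "simulation_config")
}

# deterministic per-purpose sub-seeds derived from the master seed
.sub_seed <- function(seed, stream, index = 0L) {
  (as.numeric(seed) * 48271 + stream * 104729 + index * 7919) %%
    2147483629
}

#' Sample the Wilson reference intensity set
#'
#' Enumerates the unique non-absent reflections to `d_min` and draws an
#' acentric Wilson intensity for each: exponential with mean
#' `Sigma0 * exp(-wilson_B * s^2 / 2)`, `s = 1/d`.  When an anomalous
#' signal is configured, each unique reflection also gets a Friedel
#' difference `dI` of magnitude `anom_fraction * I` with a random sign.
#'
#' @param config a [simulation_config()].
#' @return data.frame `(h, k, l, d, I_true, dI)` of canonical indices.
#' @export
sample_reference_intensities <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  # truth intensities live on Friedel-merged uniques regardless of how the
  # data will later be merged: mates share one intensity (plus ±dI/2)
  sg_merged <- as_space_group(config$sg, friedel_merged = TRUE)
  ref <- enumerate_unique_hkl(config$cell0, sg_merged, config$d_min)
  if (nrow(ref) == 0)
    stop("no reflections inside d_min = ", config$d_min, " A")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.sub_seed(config$seed, 1L))
  s2 <- 1 / ref$d^2
  mean_I <- config$wilson_Sigma0 * exp(-config$wilson_B * s2 / 2)
  ref$I_true <- stats::rexp(nrow(ref), rate = 1 / mean_I)
  ref$dI <- if (config$anom_fraction > 0) {
    config$anom_fraction * ref$I_true *
      sample(c(-1, 1), nrow(ref), replace = TRUE)
  } else rep(0, nrow(ref))
  ref
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate the ground truth of a simulated collection
#'
#' Samples everything that is fixed before any wedge is "collected": the
#' reference (and outlier) intensity sets, per-crystal true scale/B,
#' jittered cells, wedge starts, and which crystals are outliers.  The
#' outlier intensity set is built as
#' `Z = mu + rho (X - mu) + sqrt(1 - rho^2) (Y - mu)` with `Y` an
#' independent Wilson draw, so that `cor(Z, X) = rho` while the
#' resolution-dependent mean `mu` is preserved.
#'
#' @param config a [simulation_config()].
#' @return list of class `"ground_truth"`: `ref` (reference intensities),
#'   `outlier_ref`, `crystals` (data.frame of per-crystal parameters),
#'   `orbit` (cached observable images of each unique reflection).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ref <- sample_reference_intensities(config)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.sub_seed(config$seed, 2L))
  mu <- config$wilson_Sigma0 * exp(-config$wilson_B / (2 * ref$d^2))
  rho <- config$outlier_corr
  y <- stats::rexp(nrow(ref), rate = 1 / mu)
  outlier_I <- mu + rho * (ref$I_true - mu) + sqrt(1 - rho^2) * (y - mu)

  n <- config$n_crystals
  ids <- sprintf("xtal%03d", seq_len(n))
  k_true <- stats::runif(n, config$scale_range[1], config$scale_range[2])
  B_true <- stats::runif(n, config$B_range[1], config$B_range[2])
  wedge_start <- stats::runif(n, 0, 360)
  outlier <- rep(FALSE, n)
  if (config$n_outliers > 0)
    outlier[sample.int(n, config$n_outliers)] <- TRUE
  cells <- matrix(rep(as.numeric(config$cell0), each = n), n, 6)
  colnames(cells) <- c("a", "b", "c", "alpha", "beta", "gamma")
  cells[, 1:3] <- cells[, 1:3] +
    matrix(stats::rnorm(3 * n, 0, config$cell_jitter_sigma), n, 3)
  cells[, 4:6] <- cells[, 4:6] +
    matrix(stats::rnorm(3 * n, 0, config$angle_jitter_sigma), n, 3)
  cells[outlier, 1] <- cells[outlier, 1] + config$outlier_cell_shift

  orbit <- hkl_orbit(as.matrix(ref[, c("h", "k", "l")]), config$sg)
  structure(list(ref = ref,
                 outlier_ref = outlier_I,
                 crystals = data.frame(crystal_id = ids, k = k_true,
                                       B = B_true,
                                       wedge_start = wedge_start,
                                       outlier = outlier, cells),
                 orbit = orbit),
            class = "ground_truth")
}

#' Simulate one microcrystal's partial wedge
#'
#' Every observable symmetry image of every unique reflection receives an
#' independent uniform diffraction angle; images inside the crystal's
#' wedge are recorded on the frame their angle bin selects.  The recorded
#' intensity is `k * exp(-2 B s^2 / 4) * (I +- dI/2)` plus Gaussian noise
#' of variance `(I_model + noise_floor)`; sigma is set to that model
#' standard deviation.  Outlier crystals draw from the decorrelated
#' intensity set and the shifted cell stored in the ground truth.
#'
#' @param config a [simulation_config()].
#' @param truth a [ground_truth()] generated from the same config.
#' @param crystal_index integer in `1:n_crystals`.
#' @return a [crystal_dataset()].
#' @export
simulate_crystal <- function(config, truth, crystal_index) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "ground_truth"))
  i <- as.integer(crystal_index)
  stopifnot(i >= 1, i <= config$n_crystals)
  cr <- truth$crystals[i, ]
  cell <- unit_cell(cr$a, cr$b, cr$c, cr$alpha, cr$beta, cr$gamma)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.sub_seed(config$seed, 3L, i))

  orbit <- truth$orbit
  angle <- stats::runif(nrow(orbit), 0, 360)
  rel <- (angle - cr$wedge_start) %% 360
  inside <- rel < config$wedge_width
  obs <- orbit[inside, , drop = FALSE]
  rel <- rel[inside]
  frame <- pmin(as.integer(rel / config$wedge_width *
                             config$frames_per_wedge),
                config$frames_per_wedge - 1L)

  I_base <- if (cr$outlier) truth$outlier_ref[obs$uid] else
    truth$ref$I_true[obs$uid]
  I_base <- I_base + obs$friedel_sign * truth$ref$dI[obs$uid] / 2
  s2 <- 1 / resolution_of(cell, as.matrix(obs[, c("h", "k", "l")]))^2
  g <- cr$k * exp(-2 * cr$B * s2 / 4)
  I_model <- g * I_base
  sd_model <- sqrt(pmax(I_model, 0) + config$noise_floor)
  I_obs <- I_model + config$noise_scale * stats::rnorm(length(I_model)) *
    sd_model
  sigma <- pmax(sd_model, 1e-6)

  crystal_dataset(cr$crystal_id, cell,
                  observation_table(obs$h, obs$k, obs$l, I_obs, sigma,
                                    frame, cr$crystal_id),
                  wedge_start = cr$wedge_start,
                  wedge_width = config$wedge_width,
                  wavelength = config$wavelength)
}

#' Simulate a full collection of partial datasets
#'
#' @param config a [simulation_config()].
#' @return list with elements `datasets` (list of [crystal_dataset()]),
#'   `truth` (the [ground_truth()]), and `config`.
#' @examples
#' sim <- simulate_datasets(simulation_config(n_crystals = 3, seed = 7,
#'                                            cell0 = unit_cell(20, 22, 25)))
#' length(sim$datasets)
#' @export
simulate_datasets <- function(config) {
  truth <- ground_truth(config)
  datasets <- lapply(seq_len(config$n_crystals), function(i)
    simulate_crystal(config, truth, i))
  names(datasets) <- truth$crystals$crystal_id
  list(datasets = datasets, truth = truth, config = config)
}

#' Serialize ground truth next to the datasets
#'
#' Writes the sampled reference intensities and per-crystal parameters as
#' JSON so parameter-recovery analyses can be run on files alone.
#'
#' @param truth a [ground_truth()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(ref = truth$ref,
                            outlier_ref = truth$outlier_ref,
                            crystals = truth$crystals),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
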