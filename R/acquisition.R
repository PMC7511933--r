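#' Acquisition configuration for the simulated TOF
#'
#' @param mz_min,mz_max Mass detection range in Da (defaults 400, 2200).
#' @param mz_step Uniform m/z grid step in Da (continuous mode).
#' @param fwhm_ref Peak full width at half maximum (Da) at `mz_ref`.
#' @param mz_ref Reference m/z for the width model.
#' @param fwhm_slope Linear change in FWHM per Da of m/z.  Default 0:
#'   constant peak width across the range, which keeps the fixed-width
#'   interval extraction equally efficient for every panel target; set a
#'   positive slope for a resolution-like width increase.
#' @param baseline_amplitude Baseline intensity at `mz_min`.
#' @param baseline_decay Exponential decay constant of the baseline in Da;
#'   the default concentrates baseline below ~600 Da, mimicking the
#'   low-mass matrix/tissue background hump.
#' @param noise_sd Gaussian noise floor (standard deviation).
#' @param noise_signal_coef Signal-dependent variance coefficient:
#'   pointwise variance is `noise_sd^2 + noise_signal_coef * signal`.
#' @param noise_model `"gaussian"` (default) or `"poisson"`.
#' @param raster_width Pixel size in micrometres (metadata).
#' @return Object of class `acquisition_config`.
#' @export
acquisition_config <- function(mz_min = 400, mz_max = 2200, mz_step = 0.05,
                               fwhm_ref = 0.25, mz_ref = 1000,
                               fwhm_slope = 0,
                               baseline_amplitude = 30, baseline_decay = 150,
                               noise_sd = 2, noise_signal_coef = 0.02,
                               noise_model = c("gaussian", "poisson"),
                               raster_width = 100) {
  noise_model <- match.arg(noise_model)
  if (mz_min >= mz_max) stop("mz_min must be below mz_max")
  if (mz_step <= 0) stop("mz_step must be positive")
  if (fwhm_ref <= 0) stop("fwhm_ref must be positive")
  structure(
    list(mz_min = mz_min, mz_max = mz_max, mz_step = mz_step,
         fwhm_ref = fwhm_ref, mz_ref = mz_ref, fwhm_slope = fwhm_slope,
         baseline_amplitude = baseline_amplitude,
         baseline_decay = baseline_decay,
         noise_sd = noise_sd, noise_signal_coef = noise_signal_coef,
         noise_model = noise_model, raster_width = raster_width),
    class = "acquisition_config"
  )
}

#' Shared m/z axis for an acquisition configuration
#' @param acq An [acquisition_config()].
#' @return Numeric vector of m/z grid points.
#' @export
mz_axis <- function(acq) {
  seq(acq$mz_min, acq$mz_max, by = acq$mz_step)
}

# peak FWHM at a given m/z
.fwhm_at <- function(acq, mz) {
  pmax(acq$fwhm_ref + acq$fwhm_slope * (mz - acq$mz_ref), 1e-3)
}

.baseline_curve <- function(acq, mz) {
  acq$baseline_amplitude * exp(-(mz - acq$mz_min) / acq$baseline_decay)
}

# noise-free signal (peaks + baseline) for one pixel's amounts
.pixel_signal <- function(amounts, panel, acq, mz, ionization,
                          baseline = NULL) {
  signal <- if (is.null(baseline)) .baseline_curve(acq, mz) else baseline
  active <- which(amounts > 0 & ionization[panel$species_id] > 0)
  for (i in active) {
    center <- panel$target_mz[i]
    if (center < acq$mz_min || center > acq$mz_max) next
    sigma <- .fwhm_at(acq, center) / (2 * sqrt(2 * log(2)))
    lo <- max(1L, ceiling((center - 5 * sigma - acq$mz_min) / acq$mz_step) + 1L)
    hi <- min(length(mz), floor((center + 5 * sigma - acq$mz_min) / acq$mz_step) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    h <- amounts[i] * ionization[[panel$species_id[i]]]
    signal[idx] <- signal[idx] + h * exp(-(mz[idx] - center)^2 / (2 * sigma^2))
  }
  signal
}

# deterministic per-pixel noise seed below 2^31
.pixel_seed <- function(seed, pixel_index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(pixel_index) * 104729) %%
               2147483629)
}

#' Render one pixel's mass spectrum
#'
#' Sums, over all species with non-zero amount, a Gaussian peak at the
#' species target m/z scaled by `amount * ionization_factor`, adds a
#' smooth exponentially decaying baseline and pixel-seeded noise, and
#' clips at zero.
#'
#' @param amounts Named numeric vector of species amounts for one pixel
#'   (names = species_id), e.g. one column of [species_amounts()].
#' @param panel An [expected_species()] panel.
#' @param acq An [acquisition_config()].
#' @param ionization Named ionization factors (species_id -> factor).
#' @param seed Dataset seed; combined with `pixel_index` for reproducible
#'   per-pixel noise.  `NULL` for noise-free rendering.
#' @param pixel_index Pixel number within the dataset.
#' @return List with `mz` and `intensity` vectors.
#' @export
render_spectrum <- function(amounts, panel, acq, ionization,
                            seed = NULL, pixel_index = 1L) {
  mz <- mz_axis(acq)
  outside <- panel$target_mz < acq$mz_min | panel$target_mz > acq$mz_max
  if (any(outside & amounts[panel$species_id] > 0)) {
    warning("skipping species outside acquisition range: ",
            paste(panel$species_id[outside], collapse = ", "))
  }
  signal <- .pixel_signal(amounts, panel, acq, mz, ionization)
  intensity <- .add_noise(signal, acq, seed, pixel_index)
  list(mz = mz, intensity = intensity)
}

.add_noise <- function(signal, acq, seed, pixel_index) {
  if (is.null(seed) || (acq$noise_sd == 0 && acq$noise_model == "gaussian")) {
    return(pmax(signal, 0))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(.pixel_seed(seed, pixel_index))
  if (acq$noise_model == "poisson") {
    out <- stats::rpois(length(signal), lambda = pmax(signal, 0))
  } else {
    sd_vec <- sqrt(acq$noise_sd^2 + acq$noise_signal_coef * pmax(signal, 0))
    out <- signal + stats::rnorm(length(signal), 0, sd_vec)
  }
  pmax(out, 0)
}

#' Render a complete EA-IMS dataset
#'
#' @inheritParams species_amounts
#' @param acq An [acquisition_config()].
#' @param seed Dataset seed (integer).
#' @return Object of class `ims_dataset`: list with `mz`, `intensity`
#'   (matrix `n_mz x n_pixels`, float-precision values), `coords`
#'   (pixel x/y, row-major), and `metadata` (condition name, incubation
#'   time, seed, pixel size, grid dimensions).
#' @export
render_dataset <- function(phantom, activity, condition, panel, acq, seed = 1) {
  coords <- phantom_coords(phantom)
  amounts <- species_amounts(phantom, activity, condition, panel)
  mz <- mz_axis(acq)
  n_pix <- nrow(coords)
  baseline <- .baseline_curve(acq, mz)
  intensity <- matrix(0, nrow = length(mz), ncol = n_pix)
  for (p in seq_len(n_pix)) {
    signal <- .pixel_signal(amounts[, p], panel, acq, mz,
                            activity$ionization, baseline)
    intensity[, p] <- .add_noise(signal, acq, seed, p)
  }
  structure(
    list(mz = mz, intensity = intensity, coords = coords[, c("x", "y")],
         metadata = list(condition = condition$name,
                         time_min = condition$time_min,
                         attenuation = condition$attenuation,
                         seed = seed,
                         pixel_size = phantom$pixel_size,
                         height = nrow(phantom$labels),
                         width = ncol(phantom$labels))),
    class = "ims_dataset"
  )
}

#' @export
print.ims_dataset <- function(x, ...) {
  cat("IMS dataset:", ncol(x$intensity), "pixels x", length(x$mz),
      "m/z points;", x$metadata$condition, "@", x$metadata$time_min, "min\n")
  invisible(x)
}

#' Simulate a complete EA-IMS study
#'
#' One dataset per active incubation time plus a heat-inactivated and a
#' no-substrate control, all sharing the phantom and deterministic
#' per-dataset seeds derived from the master seed.
#'
#' @inheritParams render_dataset
#' @param times Active incubation times in minutes.
#' @param control_time Incubation time for the two controls.
#' @param controls Character vector of control conditions to include.
#' @param seed Master seed.
#' @param out_dir If non-`NULL`, each dataset is written as an imzML/ibd
#'   pair under this directory and file paths are returned in place of
#'   in-memory datasets.
#' @return Named list of `ims_dataset` objects (or imzML paths), class
#'   `ea_study`.
#' @export
make_study <- function(panel, phantom, activity, acq,
                       times = c(5, 15, 60, 120),
                       controls = c("heat_inactivated", "no_substrate"),
                       control_time = 60,
                       seed = 1, out_dir = NULL) {
  specs <- lapply(times, function(t) ea_condition("active", time_min = t))
  names(specs) <- sprintf("active_t%03d", times)
  for (ctrl in controls) {
    specs[[sprintf("%s_t%03d", ctrl, control_time)]] <-
      ea_condition(ctrl, time_min = control_time)
  }
  out <- vector("list", length(specs))
  names(out) <- names(specs)
  for (i in seq_along(specs)) {
    ds_seed <- as.integer((as.numeric(seed) * 7919 + i * 15485863) %% 2147483629)
    ds <- render_dataset(phantom, activity, specs[[i]], panel, acq, seed = ds_seed)
    if (is.null(out_dir)) {
      out[[i]] <- ds
    } else {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      path <- file.path(out_dir, names(specs)[i])
      write_imzml(ds, path)
      out[[i]] <- paste0(path, ".imzML")
    }
  }
  structure(out, class = "ea_study", seed = seed)
}
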