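#' Preprocessing configuration
#'
#' Defaults mirror a standard MALDI-imaging import pipeline: convolution
#' baseline removal with width 20 axis points, medium smoothing, and mean
#' interval processing with a +/- 0.156 Da window per target mass.
#'
#' @param baseline_width Baseline kernel width in axis points.
#' @param smoothing One of `"none"`, `"weak"`, `"medium"`, `"strong"`.
#' @param interval_half_width Half width of the extraction window in Da.
#' @param interval_statistic `"mean"` (default), `"max"` or `"sum"`.
#' @param normalization `"none"` (default) or `"TIC"`.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_width = 20,
                              smoothing = c("medium", "none", "weak", "strong"),
                              interval_half_width = 0.156,
                              interval_statistic = c("mean", "max", "sum"),
                              normalization = c("none", "TIC")) {
  smoothing <- match.arg(smoothing)
  interval_statistic <- match.arg(interval_statistic)
  normalization <- match.arg(normalization)
  if (baseline_width < 1) stop("baseline width must be >= 1 point")
  if (interval_half_width <= 0) stop("interval half width must be positive")
  structure(
    list(baseline_width = as.integer(baseline_width), smoothing = smoothing,
         interval_half_width = interval_half_width,
         interval_statistic = interval_statistic,
         normalization = normalization),
    class = "preprocess_config"
  )
}

#' Hash of a preprocessing configuration
#'
#' Used to guarantee that datasets compared against each other were
#' processed identically.
#'
#' @param config A [preprocess_config()].
#' @return Character MD5 hash.
#' @export
preprocess_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(config), unlist(config), sep = "=",
                   collapse = ";"), tmp)
  unname(tools::md5sum(tmp))
}

# running min/max and running mean over +/- w rows (columns = pixel
# spectra, processed independently); compiled, edge windows shrink
.roll_extreme <- function(x, w, maximum = FALSE) {
  if (w < 1 || nrow(x) < 2) return(x)
  .cpp_roll_extreme(x, as.integer(w), maximum)
}

.roll_mean <- function(x, w) {
  if (w < 1 || nrow(x) < 2) return(x)
  .cpp_roll_mean(x, as.integer(w))
}

#' Remove the spectral baseline
#'
#' Estimates the baseline by an iterative clipped minimum-convolution: a
#' morphological opening (running minimum then running maximum) with the
#' configured width, smoothed by a running mean of the same width and
#' clipped from above by the signal, repeated until stable.  The estimate
#' is subtracted and negative values are clipped to zero.  Peaks narrower
#' than the kernel are removed from the baseline estimate; smooth
#' structure wider than the kernel is treated as baseline.
#'
#' @param intensity Numeric vector (one spectrum) or matrix
#'   `n_mz x n_pixels`.
#' @param width Kernel width in axis points (default from
#'   [preprocess_config()]).
#' @param iterations Number of clip-and-smooth refinement passes.
#' @return Corrected intensities, same shape as the input.
#' @export
baseline_remove <- function(intensity, width = 20, iterations = 2) {
  vec <- is.null(dim(intensity))
  x <- if (vec) matrix(intensity, ncol = 1) else intensity
  if (width >= nrow(x)) {
    stop("baseline kernel width (", width, ") must be narrower than the axis (",
         nrow(x), " points)")
  }
  w <- max(1L, as.integer(width) %/% 2L)
  out <- .cpp_baseline_correct(x, w, max(1L, as.integer(iterations)))
  if (vec) out[, 1] else out
}

# ordinal smoothing strength -> Gaussian kernel sd in axis points
.smoothing_sd <- c(none = 0, weak = 1, medium = 2, strong = 4)

#' Smooth spectra
#'
#' Gaussian kernel smoothing; the ordinal strength maps to a kernel
#' standard deviation in axis points (none = identity, weak = 1,
#' medium = 2, strong = 4).  The kernel is normalized and edges are
#' handled by reflection, so the total ion current is preserved.
#'
#' @inheritParams baseline_remove
#' @param strength `"none"`, `"weak"`, `"medium"` or `"strong"`.
#' @return Smoothed intensities, same shape as the input.
#' @export
smooth_spectrum <- function(intensity, strength = "medium") {
  sd_pts <- .smoothing_sd[[strength]]
  if (sd_pts == 0) return(intensity)
  vec <- is.null(dim(intensity))
  x <- if (vec) matrix(intensity, ncol = 1) else intensity
  half <- ceiling(3 * sd_pts)
  kernel <- stats::dnorm(-half:half, sd = sd_pts)
  kernel <- kernel / sum(kernel)
  out <- .cpp_convolve(x, kernel)
  if (vec) out[, 1] else out
}

#' Interval intensity at a target mass
#'
#' Evaluates the configured statistic (mean by default) of the intensities
#' within the closed window `[target - hw, target + hw]`; grid points
#' exactly on a boundary are included.  A window that lies entirely
#' outside the axis yields 0 with a warning; a window partially outside is
#' truncated.
#'
#' @param mz m/z axis vector.
#' @param intensity Vector (one spectrum) or matrix `n_mz x n_pixels`.
#' @param target Target m/z in Da.
#' @param half_width Window half width in Da.
#' @param statistic `"mean"`, `"max"` or `"sum"`.
#' @return A scalar (vector input) or one value per pixel (matrix input).
#' @export
interval_intensity <- function(mz, intensity, target, half_width = 0.156,
                               statistic = c("mean", "max", "sum")) {
  statistic <- match.arg(statistic)
  vec <- is.null(dim(intensity))
  x <- if (vec) matrix(intensity, ncol = 1) else intensity
  tol <- 1e-9
  idx <- which(mz >= target - half_width - tol & mz <= target + half_width + tol)
  if (length(idx) == 0) {
    warning(sprintf("interval around m/z %.4f lies outside the axis", target))
    return(if (vec) 0 else rep(0, ncol(x)))
  }
  window <- x[idx, , drop = FALSE]
  if (anyNA(window)) stop("NaN/NA intensity inside the extraction window")
  out <- switch(statistic,
                mean = colMeans(window),
                max = apply(window, 2, max),
                sum = colSums(window))
  if (vec) out[[1]] else unname(out)
}

#' Preprocess one dataset
#'
#' Applies baseline removal, optional TIC normalization and smoothing to
#' every pixel spectrum, and records the configuration hash so that only
#' identically processed datasets are compared downstream.
#'
#' @param dataset An `ims_dataset`.
#' @param config A [preprocess_config()].
#' @return The dataset with corrected intensities and a `preprocess`
#'   element (`config`, `hash`).
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  x <- baseline_remove(dataset$intensity, config$baseline_width)
  if (config$normalization == "TIC") {
    tic <- colSums(x)
    tic[tic == 0] <- 1
    x <- sweep(x, 2, mean(tic) / tic, `*`)
  }
  x <- smooth_spectrum(x, config$smoothing)
  dataset$intensity <- x
  dataset$preprocess <- list(config = config, hash = preprocess_hash(config))
  dataset
}

#' Preprocess a study and extract the per-target pixel table
#'
#' Applies one configuration to every dataset of a study (identical
#' settings across datasets keep them comparable) and extracts, for every
#' panel species and pixel, the interval intensity at the species target
#' m/z.
#'
#' @param study A named list of `ims_dataset` objects ([make_study()]).
#' @param panel An [expected_species()] panel.
#' @param config A [preprocess_config()].
#' @return List with `datasets` (preprocessed) and `targets` (long data
#'   frame: dataset, condition, time_min, x, y, species_id, intensity).
#' @export
preprocess_study <- function(study, panel, config = preprocess_config()) {
  axes <- lapply(study, function(d) d$mz)
  for (i in seq_along(axes)[-1]) {
    if (length(axes[[i]]) != length(axes[[1]]) ||
        any(axes[[i]] != axes[[1]])) {
      stop("m/z axis mismatch between datasets; cannot preprocess as a study")
    }
  }
  processed <- lapply(study, preprocess_dataset, config = config)
  tables <- lapply(names(processed), function(nm) {
    ds <- processed[[nm]]
    per_species <- lapply(seq_len(nrow(panel)), function(i) {
      data.frame(
        dataset = nm,
        condition = ds$metadata$condition,
        time_min = ds$metadata$time_min,
        x = ds$coords$x, y = ds$coords$y,
        species_id = panel$species_id[i],
        intensity = interval_intensity(ds$mz, ds$intensity,
                                       panel$target_mz[i],
                                       config$interval_half_width,
                                       config$interval_statistic),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per_species)
  })
  list(datasets = processed, targets = do.call(rbind, tables),
       hash = preprocess_hash(config))
}

#' Estimate the intensity noise scale from off-target windows
#'
#' Samples interval intensities at window centers away from every panel
#' target and summarizes their distribution.  The center (median) captures
#' the positive offset that baseline clipping leaves in signal-free
#' windows; the scale (MAD) is the pixel-to-pixel noise of a signal-free
#' window.  Both are needed to convert a species' mean window intensity
#' into a signal-to-noise ratio.
#'
#' @param dataset A preprocessed `ims_dataset`.
#' @param panel An [expected_species()] panel (targets to avoid).
#' @param config A [preprocess_config()].
#' @param n_windows Number of off-target windows to sample.
#' @param exclusion Minimum distance from any panel target in Da.
#' @return List with `center`, `scale` and the sampled `values`.
#' @export
estimate_noise <- function(dataset, panel, config = preprocess_config(),
                           n_windows = 50, exclusion = 1) {
  rng <- range(dataset$mz)
  centers <- seq(rng[1] + 2, rng[2] - 2, length.out = n_windows * 3)
  keep <- vapply(centers, function(cc) {
    all(abs(cc - panel$target_mz) > exclusion)
  }, TRUE)
  centers <- utils::head(centers[keep], n_windows)
  values <- unlist(lapply(centers, function(cc) {
    interval_intensity(dataset$mz, dataset$intensity, cc,
                       config$interval_half_width, config$interval_statistic)
  }))
  scale <- stats::mad(values)
  if (scale == 0) scale <- stats::sd(values)
  if (is.na(scale) || scale == 0) scale <- 1e-6
  list(center = stats::median(values), scale = scale, values = values)
}
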