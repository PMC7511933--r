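#' Ion image for one species
#'
#' Arranges the per-pixel interval intensity at the species target m/z on
#' the acquisition grid.
#'
#' @param dataset A preprocessed `ims_dataset`.
#' @param species One row of an [expected_species()] panel (or a list with
#'   `species_id` and `target_mz`).
#' @param config A [preprocess_config()] (interval settings).
#' @return Object of class `ion_image`: list with `values` (matrix
#'   `height x width`, off-grid pixels `NA`), `species_id`, `condition`,
#'   `time_min`.
#' @export
ion_image <- function(dataset, species, config = preprocess_config()) {
  target <- species$target_mz
  if (target < min(dataset$mz) || target > max(dataset$mz)) {
    stop(sprintf("species target m/z %.4f outside acquired range [%g, %g]",
                 target, min(dataset$mz), max(dataset$mz)))
  }
  vals <- interval_intensity(dataset$mz, dataset$intensity, target,
                             config$interval_half_width,
                             config$interval_statistic)
  h <- dataset$metadata$height
  w <- dataset$metadata$width
  img <- matrix(NA_real_, h, w)
  img[cbind(dataset$coords$y, dataset$coords$x)] <- vals
  structure(
    list(values = img, species_id = species$species_id,
         condition = dataset$metadata$condition,
         time_min = dataset$metadata$time_min),
    class = "ion_image"
  )
}

#' Conversion map (product fraction) for one substrate
#'
#' Computes, per pixel, the product fraction `sum(P) / (sum(P) + S)` from
#' the substrate ion image and the ion images of its products.  Pixels
#' whose total signal `sum(P) + S` falls below `floor` carry no reliable
#' conversion information and are marked undefined.
#'
#' @param substrate_image `ion_image` of the substrate.
#' @param product_images List of `ion_image`s of the substrate's products
#'   (their intensities are summed; pass a single image for a per-product
#'   map).
#' @param floor Definition threshold on `sum(P) + S` (intensity units).
#' @return Object of class `conversion_map`: `values` matrix with product
#'   fractions in `[0, 1]` (`NA` where undefined) and the logical
#'   `defined` mask.
#' @export
conversion_map <- function(substrate_image, product_images, floor = 0) {
  if (inherits(product_images, "ion_image")) {
    product_images <- list(product_images)
  }
  s <- substrate_image$values
  for (img in product_images) {
    if (!all(dim(img$values) == dim(s))) {
      stop("substrate and product images are on different grids")
    }
  }
  p <- Reduce(`+`, lapply(product_images, `[[`, "values"))
  total <- p + s
  defined <- !is.na(total) & total >= floor & total > 0
  frac <- ifelse(defined, p / total, NA_real_)
  frac[defined] <- pmin(pmax(frac[defined], 0), 1)
  structure(
    list(values = frac, defined = defined,
         substrate_id = sub("^s([0-9]+).*", "\\1", substrate_image$species_id),
         condition = substrate_image$condition,
         time_min = substrate_image$time_min, floor = floor),
    class = "conversion_map"
  )
}

.image_values <- function(image) {
  if (inherits(image, c("ion_image", "conversion_map"))) image$values
  else image
}

#' Region-of-interest pixel statistics
#'
#' Summarizes the pixel values of an ion image or conversion map within
#' each phantom region: the values behind the per-pixel dot plots and
#' their box-plot summaries.
#'
#' @param image An `ion_image`, `conversion_map` or plain matrix on the
#'   phantom grid.
#' @param phantom A [make_phantom()] phantom.
#' @param regions Integer region labels (default: all on-tissue regions).
#' @param keep_values Also return the raw per-pixel values per region.
#' @return Data frame with one row per region: `region`, `region_name`,
#'   `n_pixels`, `mean`, `median`, `q1`, `q3`, `min`, `max`.  Empty
#'   regions yield an explicit `n_pixels = 0` row.  With
#'   `keep_values = TRUE`, a list with `stats` and `pixels`.
#' @export
roi_stats <- function(image, phantom, regions = NULL, keep_values = FALSE) {
  vals <- .image_values(image)
  if (!all(dim(vals) == dim(phantom$labels))) {
    stop("image and phantom are on different grids")
  }
  if (is.null(regions)) {
    regions <- setdiff(sort(unique(as.integer(phantom$labels))), 0L)
  }
  rows <- lapply(regions, function(reg) {
    name <- unname(phantom$region_names[as.character(reg)])
    if (length(name) == 0 || is.na(name)) name <- NA_character_
    v <- vals[phantom$labels == reg]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      return(data.frame(region = reg, region_name = name,
                        n_pixels = 0L, mean = NA_real_, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_, min = NA_real_,
                        max = NA_real_, stringsAsFactors = FALSE))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(region = reg, region_name = name,
               n_pixels = length(v), mean = mean(v), median = q[2],
               q1 = q[1], q3 = q[3], min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  if (!keep_values) return(stats)
  pixels <- lapply(stats::setNames(regions, regions), function(reg) {
    v <- vals[phantom$labels == reg]
    v[!is.na(v)]
  })
  list(stats = stats, pixels = pixels)
}

#' Time course of a species' regional intensity
#'
#' Mean (and median) interval intensity of one species within one region,
#' per incubation time, with the control conditions included as extra
#' rows.
#'
#' @param study Named list of preprocessed `ims_dataset`s.
#' @param panel An [expected_species()] panel.
#' @param species_id Species to follow.
#' @param phantom The study phantom.
#' @param region Region label (default 0 means all on-tissue pixels).
#' @param config A [preprocess_config()].
#' @return Data frame: `dataset`, `condition`, `time_min`, `n_pixels`,
#'   `mean_intensity`, `median_intensity`, ordered by condition and time.
#' @export
time_course <- function(study, panel, species_id, phantom, region = 0,
                        config = preprocess_config()) {
  sp <- panel[panel$species_id == species_id, ]
  if (nrow(sp) != 1) stop("unknown species_id: ", species_id)
  mask <- if (region == 0) phantom$labels > 0 else phantom$labels == region
  rows <- lapply(names(study), function(nm) {
    ds <- study[[nm]]
    img <- ion_image(ds, sp, config)
    v <- img$values[mask]
    v <- v[!is.na(v)]
    data.frame(dataset = nm, condition = ds$metadata$condition,
               time_min = ds$metadata$time_min, n_pixels = length(v),
               mean_intensity = mean(v), median_intensity = stats::median(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$condition != "active", out$time_min), ]
}

#' Grade species detectability from pixel intensities
#'
#' Converts a species' on-tissue pixel intensities into the ordinal
#' detectability grades used for substrate panels: `-` (not detected),
#' `+`, `++`, `+++`.  The score is a background-corrected signal-to-noise
#' ratio, `(mean(values) - noise$center) / noise$scale`; species below
#' `snr_min` grade `-`, and each further decade (default `factor = 10`)
#' raises the grade.
#'
#' @param values Numeric pixel intensities (on-tissue) for one species.
#' @param noise Noise estimate from [estimate_noise()] (list with `center`
#'   and `scale`), or a single scale value (center 0).
#' @param snr_min SNR below which a species is graded `-` (default 3).
#' @param factor Multiplicative threshold between successive grades.
#' @return List with `grade`, `snr` and the thresholds used.
#' @export
grade_detectability <- function(values, noise, snr_min = 3, factor = 10) {
  if (is.numeric(noise)) noise <- list(center = 0, scale = noise)
  if (noise$scale <= 0) stop("noise scale must be positive")
  snr <- (mean(values, na.rm = TRUE) - noise$center) / noise$scale
  thresholds <- snr_min * factor^(0:2)
  grade <- if (snr < thresholds[1]) "-" else
    if (snr < thresholds[2]) "+" else
      if (snr < thresholds[3]) "++" else "+++"
  list(grade = grade, snr = snr, thresholds = thresholds)
}

#' Grade every panel species in a dataset
#'
#' @param dataset A preprocessed `ims_dataset`.
#' @param panel An [expected_species()] panel.
#' @param phantom The study phantom (defines on-tissue pixels).
#' @param config A [preprocess_config()].
#' @param noise Optional precomputed [estimate_noise()] result.
#' @inheritParams grade_detectability
#' @return Data frame: `species_id`, `role`, `snr`, `grade`.
#' @export
grade_panel <- function(dataset, panel, phantom, config = preprocess_config(),
                        noise = NULL, snr_min = 3, factor = 10) {
  if (is.null(noise)) noise <- estimate_noise(dataset, panel, config)
  mask <- phantom$labels > 0
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    img <- ion_image(dataset, panel[i, ], config)
    g <- grade_detectability(img$values[mask], noise, snr_min, factor)
    data.frame(species_id = panel$species_id[i], role = panel$role[i],
               snr = g$snr, grade = g$grade, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "noise") <- noise[c("center", "scale")]
  attr(out, "thresholds") <- snr_min * factor^(0:2)
  out
}

#' Contrast a species between two conditions
#'
#' Compares the regional pixel intensities of one species between an
#' active dataset and a control (heat-inactivated or no-substrate):
#' difference of region means, their ratio, and a rank-based effect size
#' (Cliff's delta, in `[-1, 1]`).  No hypothesis-testing machinery —
#' the outputs are descriptive, as regional dot/box plot comparisons are.
#'
#' @param active,control Preprocessed `ims_dataset`s on the same grid and
#'   with the same preprocessing hash.
#' @param species One panel row.
#' @param phantom The study phantom.
#' @param region Region label (0 = all on-tissue).
#' @param config A [preprocess_config()].
#' @return Data frame row: species, conditions, means, `difference`,
#'   `ratio`, `cliffs_delta`.
#' @export
condition_contrast <- function(active, control, species, phantom, region = 0,
                               config = preprocess_config()) {
  ha <- active$preprocess$hash
  hc <- control$preprocess$hash
  if (!is.null(ha) && !is.null(hc) && !identical(ha, hc)) {
    stop("preprocessing configuration mismatch between datasets")
  }
  if (!all(dim(active$intensity) == dim(control$intensity))) {
    stop("datasets have different grids")
  }
  mask <- if (region == 0) phantom$labels > 0 else phantom$labels == region
  va <- ion_image(active, species, config)$values[mask]
  vc <- ion_image(control, species, config)$values[mask]
  va <- va[!is.na(va)]
  vc <- vc[!is.na(vc)]
  # Cliff's delta from the Mann-Whitney U statistic
  u <- sum(rank(c(va, vc))[seq_along(va)]) - length(va) * (length(va) + 1) / 2
  delta <- 2 * u / (length(va) * length(vc)) - 1
  data.frame(
    species_id = species$species_id,
    active_condition = active$metadata$condition,
    control_condition = control$metadata$condition,
    mean_active = mean(va), mean_control = mean(vc),
    difference = mean(va) - mean(vc),
    ratio = mean(va) / ifelse(mean(vc) == 0, NA_real_, mean(vc)),
    cliffs_delta = delta,
    stringsAsFactors = FALSE
  )
}
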