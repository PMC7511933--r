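#' Kidney-like tissue phantom
#'
#' Builds a pixelated phantom with a background border, a cortex annulus
#' and a medulla core, standing in for a transverse kidney section with
#' its two anatomical ROIs.  The region boundary is an ellipse with a
#' small seeded angular perturbation so that repeated seeds give varied
#' but reproducible shapes.
#'
#' @param height,width Grid dimensions in pixels (>= 8 each).
#' @param seed Integer seed controlling the boundary perturbation.
#' @param pixel_size Raster width in micrometres (metadata only).
#' @return An object of class `tissue_phantom`: list with `labels`
#'   (integer matrix, 0 = off-tissue, 1 = cortex, 2 = medulla),
#'   `pixel_size`, and `region_names`.
#' @export
make_phantom <- function(height = 32, width = 32, seed = 1, pixel_size = 100) {
  if (height < 8 || width < 8) {
    stop("phantom dimensions must be at least 8 x 8")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  phase <- stats::runif(2, 0, 2 * pi)
  wobble <- stats::runif(1, 0.02, 0.06)

  cy <- (height + 1) / 2
  cx <- (width + 1) / 2
  ry <- 0.44 * height
  rx <- 0.44 * width
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  theta <- atan2((yy - cy) / ry, (xx - cx) / rx)
  r <- sqrt(((yy - cy) / ry)^2 + ((xx - cx) / rx)^2)
  edge <- 1 + wobble * sin(3 * theta + phase[1])
  core <- 0.5 * (1 + wobble * sin(2 * theta + phase[2]))

  labels <- matrix(0L, height, width)
  labels[r <= edge] <- 1L
  labels[r <= core] <- 2L
  if (!all(c(0L, 1L, 2L) %in% labels)) {
    # degenerate wobble draw; fall back to unperturbed ellipses
    labels <- matrix(0L, height, width)
    labels[r <= 1] <- 1L
    labels[r <= 0.5] <- 2L
  }

  structure(
    list(labels = labels, pixel_size = pixel_size,
         region_names = c(`1` = "cortex", `2` = "medulla"), seed = seed),
    class = "tissue_phantom"
  )
}

#' @export
print.tissue_phantom <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:2,
                      labels = c("off-tissue", "cortex", "medulla")))
  cat("Tissue phantom", nrow(x$labels), "x", ncol(x$labels),
      "px (", x$pixel_size, "um/px):",
      paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

#' Pixel coordinates of a phantom grid
#'
#' Pixels are enumerated row-major (y outer, x inner), 1-based, matching
#' the order in which spectra are rendered and stored.
#'
#' @param phantom A `tissue_phantom` (or any object with a `labels` matrix).
#' @return Data frame with `x`, `y` and the region `label` per pixel.
#' @export
phantom_coords <- function(phantom) {
  labels <- phantom$labels
  h <- nrow(labels)
  w <- ncol(labels)
  data.frame(
    x = rep(seq_len(w), times = h),
    y = rep(seq_len(h), each = w),
    label = as.integer(t(labels))
  )
}
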