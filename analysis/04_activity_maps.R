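#!/usr/bin/env Rscript

# Derive the study outputs: ion images and conversion maps for the
# substrates with regional activity, ROI (cortex vs medulla) statistics,
# product time courses, detectability grades, and control contrasts.
# Outputs: results/maps/*.tsv, results/figures/*.png,
#          results/{roi_stats,time_courses,grades,contrasts}.tsv

library(eaims)

cfg <- read_run_config("analysis/config.yaml")
lib <- load_library(cfg$library)
pan <- expected_species(lib)
phantom <- make_phantom(cfg$phantom$height, cfg$phantom$width,
                        seed = cfg$seed, pixel_size = cfg$phantom$pixel_size)

paths <- Sys.glob("scratch/study/*.imzML")
if (length(paths) == 0) {
  stop("no study found under scratch/study; run analysis/02_simulate_study.R first")
}
study <- lapply(paths, read_imzml)
names(study) <- sub("\\.imzML$", "", basename(paths))
prep <- preprocess_study(study, pan, cfg$preprocess)
datasets <- prep$datasets
prov <- list(seed = cfg$seed, config_md5 = attr(cfg, "config_md5"),
             library_md5 = attr(lib, "library_md5"),
             preprocess_hash = prep$hash)

# substrates followed in detail: regionally contrasted enzymes
focus <- c(6, 7, 12, 19, 4, 8, 20)
active60 <- datasets$active_t060

matrix_to_tsv <- function(m, path) {
  df <- as.data.frame(m)
  names(df) <- sprintf("x%02d", seq_len(ncol(m)))
  write_tsv_provenance(df, path, prov)
}

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
png_map <- function(values, path, main) {
  grDevices::png(path, width = 480, height = 480)
  graphics::image(t(values[nrow(values):1, ]), axes = FALSE, main = main,
                  col = grDevices::hcl.colors(64, "viridis"))
  grDevices::dev.off()
}

roi_rows <- list()
map_rows <- list()
for (sid in focus) {
  rows <- pan[pan$substrate_id == sid, ]
  sub_img <- ion_image(active60, rows[rows$role == "substrate", ],
                       cfg$preprocess)
  prod_imgs <- lapply(which(rows$role != "substrate"), function(i) {
    ion_image(active60, rows[i, ], cfg$preprocess)
  })
  cm <- conversion_map(sub_img, prod_imgs, floor = cfg$analysis$floor)

  matrix_to_tsv(sub_img$values,
                sprintf("results/maps/s%02d_substrate.tsv", sid))
  matrix_to_tsv(cm$values, sprintf("results/maps/s%02d_conversion.tsv", sid))
  png_map(sub_img$values, sprintf("results/figures/s%02d_substrate.png", sid),
          sprintf("substrate %d, 60 min", sid))
  png_map(cm$values, sprintf("results/figures/s%02d_conversion.png", sid),
          sprintf("conversion map, substrate %d", sid))

  st <- roi_stats(cm, phantom)
  st$substrate_id <- sid
  roi_rows[[length(roi_rows) + 1]] <- st
  map_rows[[length(map_rows) + 1]] <- data.frame(
    substrate_id = sid,
    defined_pixels = sum(cm$defined),
    median_conversion = stats::median(cm$values, na.rm = TRUE))
}
roi_all <- do.call(rbind, roi_rows)
write_tsv_provenance(roi_all, "results/roi_stats.tsv", prov)
message("Conversion medians at 60 min (cortex vs medulla):")
print(stats::reshape(roi_all[, c("substrate_id", "region_name", "median")],
                     idvar = "substrate_id", timevar = "region_name",
                     direction = "wide"), row.names = FALSE)

# time courses of every focus product in both regions
tc_rows <- list()
for (sid in focus) {
  prods <- pan[pan$substrate_id == sid & pan$role != "substrate", ]
  for (i in seq_len(nrow(prods))) {
    for (reg in c(1, 2)) {
      tc <- time_course(datasets, pan, prods$species_id[i], phantom,
                        region = reg, config = cfg$preprocess)
      tc$species_id <- prods$species_id[i]
      tc$region <- reg
      tc_rows[[length(tc_rows) + 1]] <- tc
    }
  }
}
write_tsv_provenance(do.call(rbind, tc_rows), "results/time_courses.tsv", prov)

# detectability grades per dataset
grade_rows <- lapply(names(datasets), function(nm) {
  g <- grade_panel(datasets[[nm]], pan, phantom, cfg$preprocess)
  g$dataset <- nm
  g
})
grades <- do.call(rbind, grade_rows)
write_tsv_provenance(grades, "results/grades.tsv", prov)
g60 <- grades[grades$dataset == "active_t060", ]
message(sprintf(
  "Active 60 min: %d/%d substrates and %d/%d products graded detectable",
  sum(g60$grade != "-" & g60$role == "substrate"), 20,
  sum(g60$grade != "-" & g60$role != "substrate"), 34))

# contrasts against the two controls
contrast_rows <- list()
for (sid in focus) {
  rows <- pan[pan$substrate_id == sid, ]
  for (ctrl in c("heat_inactivated_t060", "no_substrate_t060")) {
    for (i in seq_len(nrow(rows))) {
      cc <- condition_contrast(active60, datasets[[ctrl]], rows[i, ],
                               phantom, config = cfg$preprocess)
      cc$control_dataset <- ctrl
      contrast_rows[[length(contrast_rows) + 1]] <- cc
    }
  }
}
write_tsv_provenance(do.call(rbind, contrast_rows), "results/contrasts.tsv",
                     prov)
message("Wrote results/{roi_stats,time_courses,grades,contrasts}.tsv and per-substrate maps under results/maps")
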