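#' Read a run configuration
#'
#' A YAML file describing a complete run: library path, phantom and
#' activity parameters, acquisition settings, preprocessing settings,
#' analysis options and the master seed.  Missing sections fall back to
#' the package defaults; recognized sections are `library`, `phantom`,
#' `activity`, `acquisition`, `preprocess`, `analysis`, `seed`,
#' `out_dir`.
#'
#' @param path Path to the YAML file.
#' @return Object of class `run_config`: the parsed list, with defaults
#'   filled in and the file's MD5 recorded.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("run configuration not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("malformed run configuration: top level must be a map")
  known <- c("library", "phantom", "activity", "acquisition", "preprocess",
             "analysis", "seed", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown run configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg$library <- cfg$library %||%
    system.file("extdata", "table1_library.tsv", package = "eaims")
  cfg$seed <- cfg$seed %||% 1L
  cfg$phantom <- utils::modifyList(
    list(height = 32, width = 32, pixel_size = 100), cfg$phantom %||% list())
  cfg$acquisition <- do.call(acquisition_config, cfg$acquisition %||% list())
  cfg$preprocess <- do.call(preprocess_config, cfg$preprocess %||% list())
  cfg$analysis <- utils::modifyList(
    list(min_mass = 600, min_separation = 0.312, tolerance = 0.05,
         snr_min = 3, grade_factor = 10, floor = 0),
    cfg$analysis %||% list())
  attr(cfg, "config_md5") <- unname(tools::md5sum(path))
  class(cfg) <- "run_config"
  cfg
}

#' Write a table with a provenance header
#'
#' Every persistent output carries a provenance block (commented header
#' lines) naming the package version, the seed, and the hashes of the
#' run configuration and substrate library that produced it, so any
#' table can be traced back to its run.
#'
#' @param x Data frame to write.
#' @param path Output TSV path.
#' @param provenance Named list of provenance fields (seed, hashes, ...).
#' @return Invisibly, `path`.
#' @export
write_tsv_provenance <- function(x, path, provenance = list()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  fields <- c(list(tool = paste0("eaims ", as.character(
    utils::packageVersion("eaims"))),
    written = "deterministic-output"), provenance)
  header <- sprintf("# %s: %s", names(fields),
                    vapply(fields, function(v) paste(as.character(v),
                                                     collapse = ","), ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  suppressWarnings(utils::write.table(x, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' Read back a provenance-headed TSV
#'
#' @param path Path written by [write_tsv_provenance()].
#' @return Data frame; provenance lines in attribute `provenance`.
#' @export
read_tsv_provenance <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  out <- utils::read.delim(text = lines[setdiff(seq_along(lines), hdr)],
                           stringsAsFactors = FALSE)
  attr(out, "provenance") <- sub("^# ", "", lines[hdr])
  out
}
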