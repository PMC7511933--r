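# shared fixtures, built in code

table1_path <- function() {
  system.file("extdata", "table1_library.tsv", package = "eaims",
              mustWork = TRUE)
}

table1_library <- function() load_library(table1_path())

table1_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- expected_species(table1_library())
    cache
  }
})

panel_row <- function(panel, id) panel[panel$species_id == id, ]

# small acquisition window around a subset of species: keeps unit tests
# fast while exercising the same code paths as the full-range default
mini_acq <- function(...) {
  acquisition_config(mz_min = 580, mz_max = 900, ...)
}

# the three species of protease substrate 8 (no m/z collisions, all
# within the mini acquisition window except the substrate)
mini_panel <- function() {
  pan <- table1_panel()
  pan[pan$substrate_id == 8, ]
}

# brute-force O(n^2) collision oracle over target m/z values
brute_force_collisions <- function(panel, min_separation) {
  mz <- panel$target_mz
  ids <- panel$species_id
  hits <- list()
  n <- length(mz)
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      if (abs(mz[i] - mz[j]) < min_separation) {
        pair <- sort(c(ids[i], ids[j]))
        hits[[length(hits) + 1L]] <- paste(pair, collapse = "|")
      }
    }
  }
  out <- unlist(hits)
  if (is.null(out)) character(0) else sort(out)
}

# random mass panel for property tests of the collision scan
random_panel <- function(n, seed) {
  set.seed(seed)
  data.frame(
    species_id = sprintf("r%03d", seq_len(n)),
    substrate_id = seq_len(n),
    role = "substrate",
    mass_average = stats::runif(n, 600, 1800),
    stringsAsFactors = FALSE
  ) |> (\(d) { d$target_mz <- d$mass_average + 1.00727646677; d })()
}
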