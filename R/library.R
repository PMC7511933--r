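#' Load a peptide substrate library
#'
#' Reads a tab-separated substrate table (one row per applied substrate)
#' describing sequences, modifications, enzyme classes, cleavage or
#' phosphorylation sites, and the published masses and detectability
#' grades kept for regression.
#'
#' Expected columns: `id`, `sequence`, `modifications`
#' (semicolon-separated `name@position` tokens), `enzyme_class`
#' (`protease`, `kinase` or `phosphatase`), `target_enzymes`,
#' `cleavage_index` (proteases: length of the N-terminal fragment),
#' `phospho_position` (kinases/phosphatases), `printed_substrate_mass`,
#' `printed_substrate_int`, `product1_seq`, `printed_product1_mass`,
#' `printed_product1_int`, `product2_seq`, `printed_product2_mass`,
#' `printed_product2_int`.
#'
#' @param path Path to the TSV file.  The packaged library transcribing the
#'   published 20-substrate panel is at
#'   `system.file("extdata", "table1_library.tsv", package = "eaims")`.
#' @param residue_table A [residue_mass_table()] used to validate sequences.
#' @return A data frame of class `substrate_library`, with the library file
#'   MD5 in attribute `library_md5`.
#' @export
load_library <- function(path, residue_table = residue_mass_table()) {
  if (!file.exists(path)) stop("library file not found: ", path)
  lib <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                           colClasses = "character")
  required <- c("id", "sequence", "modifications", "enzyme_class",
                "target_enzymes", "cleavage_index", "phospho_position",
                "printed_substrate_mass", "printed_substrate_int",
                "product1_seq", "printed_product1_mass", "printed_product1_int",
                "product2_seq", "printed_product2_mass", "printed_product2_int")
  missing_cols <- setdiff(required, names(lib))
  if (length(missing_cols) > 0) {
    stop("library is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(lib) == 0) {
    out <- lib
    class(out) <- c("substrate_library", class(out))
    attr(out, "library_md5") <- unname(tools::md5sum(path))
    return(out)
  }

  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  int_or_na <- function(x) suppressWarnings(as.integer(x))
  lib$id <- int_or_na(lib$id)
  if (anyNA(lib$id)) stop("malformed row: non-integer id in library")
  lib$cleavage_index <- int_or_na(lib$cleavage_index)
  lib$phospho_position <- int_or_na(lib$phospho_position)
  lib$printed_substrate_mass <- num_or_na(lib$printed_substrate_mass)
  lib$printed_product1_mass <- num_or_na(lib$printed_product1_mass)
  lib$printed_product2_mass <- num_or_na(lib$printed_product2_mass)
  for (col in grep("_int$", names(lib), value = TRUE)) {
    lib[[col]][!nzchar(trimws(ifelse(is.na(lib[[col]]), "", lib[[col]])))] <- NA
  }

  alphabet <- residue_table$residues$residue
  classes <- c("protease", "kinase", "phosphatase")
  for (i in seq_len(nrow(lib))) {
    row <- lib[i, ]
    if (is.na(row$sequence) || !nzchar(row$sequence)) {
      stop("malformed row id=", row$id, ": empty sequence")
    }
    letters_ <- strsplit(row$sequence, "", fixed = TRUE)[[1]]
    bad <- setdiff(letters_, alphabet)
    if (length(bad) > 0) {
      stop("row id=", row$id, ": residue letter(s) not in alphabet: ",
           paste(unique(bad), collapse = ", "))
    }
    if (!row$enzyme_class %in% classes) {
      stop("row id=", row$id, ": unknown enzyme_class '", row$enzyme_class, "'")
    }
    if (row$enzyme_class == "protease") {
      if (is.na(row$cleavage_index)) {
        stop("row id=", row$id, ": protease substrate lacks cleavage_index")
      }
      if (row$cleavage_index < 1L || row$cleavage_index >= nchar(row$sequence)) {
        stop("row id=", row$id, ": cleavage_index out of range")
      }
    } else {
      if (is.na(row$phospho_position) ||
          row$phospho_position < 1L ||
          row$phospho_position > nchar(row$sequence)) {
        stop("row id=", row$id, ": phospho_position missing or out of range")
      }
    }
    # validates modification names and positions
    mods <- parse_modifications(row$modifications)
    if (nrow(mods) > 0) {
      peptide_mass(row$sequence, mods, "average", residue_table)
    }
  }

  class(lib) <- c("substrate_library", class(lib))
  attr(lib, "library_md5") <- unname(tools::md5sum(path))
  lib
}

#' @export
print.substrate_library <- function(x, ...) {
  cat("Substrate library:", nrow(x), "substrates (",
      sum(x$enzyme_class == "protease"), "protease,",
      sum(x$enzyme_class == "kinase"), "kinase,",
      sum(x$enzyme_class == "phosphatase"), "phosphatase )\n")
  invisible(x)
}

# strip display notation (lowercase p, '*', tags such as MCA-/-(DNP)) from a
# printed product sequence, keeping only upper-case residue letters
.strip_printed_seq <- function(x) {
  if (is.na(x)) return(NA_character_)
  x <- gsub("\\(([A-Za-z0-9]+)\\)", "", x)     # side-chain tags e.g. (DNP)
  x <- gsub("^[A-Za-z0-9]+-", "", x)           # N-terminal tags e.g. MCA-
  paste(grep("[A-Z]", strsplit(x, "", fixed = TRUE)[[1]], value = TRUE),
        collapse = "")
}

# modification data frame for one substrate row, optionally +/- phospho
.substrate_mods <- function(row) {
  parse_modifications(row$modifications)
}

#' Enumerate the measurable species expected for one substrate
#'
#' For a protease substrate, returns the substrate plus the two cleavage
#' fragments (split after `cleavage_index`; each fragment gains a water
#' through hydrolysis).  For a kinase substrate, the substrate plus its
#' phosphorylated product (+HPO3); for a phosphatase substrate, the
#' (phosphorylated) substrate plus its dephosphorylated product (-HPO3).
#'
#' @param row One-row slice of a `substrate_library`.
#' @param adduct `"M+H"` (default) to report protonated target m/z, or
#'   `"neutral"` to image neutral masses.
#' @param residue_table A [residue_mass_table()].
#' @return Data frame of expected species with computed average and
#'   monoisotopic neutral masses, `target_mz`, and the printed mass/grade
#'   (where published) retained for regression.
#' @export
enumerate_expected_species <- function(row, adduct = c("M+H", "neutral"),
                                       residue_table = residue_mass_table()) {
  adduct <- match.arg(adduct)
  stopifnot(nrow(row) == 1L)
  id <- row$id
  mods <- .substrate_mods(row)

  mass2 <- function(seq, m) c(
    average = peptide_mass(seq, m, "average", residue_table),
    monoisotopic = peptide_mass(seq, m, "monoisotopic", residue_table)
  )
  mods_string <- function(m) {
    if (nrow(m) == 0) "" else paste(m$name, m$position, sep = "@", collapse = ";")
  }

  species <- list()
  sub_mass <- mass2(row$sequence, mods)
  species[[1]] <- data.frame(
    species_id = sprintf("s%02d.substrate", id),
    substrate_id = id,
    role = "substrate",
    sequence = row$sequence,
    modifications = mods_string(mods),
    mass_average = sub_mass[["average"]],
    mass_monoisotopic = sub_mass[["monoisotopic"]],
    printed_mass = row$printed_substrate_mass,
    printed_int = row$printed_substrate_int,
    printed_sequence = row$sequence,
    stringsAsFactors = FALSE
  )

  if (row$enzyme_class == "protease") {
    if (is.na(row$cleavage_index)) {
      stop("protease substrate id=", id, " has no cleavage_index")
    }
    n <- nchar(row$sequence)
    seq1 <- substr(row$sequence, 1L, row$cleavage_index)
    seq2 <- substr(row$sequence, row$cleavage_index + 1L, n)
    if (nrow(mods) > 0) {
      stop("modified protease substrates are not supported (id=", id, ")")
    }
    m1 <- mass2(seq1, NULL)
    m2 <- mass2(seq2, NULL)
    species[[2]] <- data.frame(
      species_id = sprintf("s%02d.p1", id), substrate_id = id,
      role = "cleavage_product_1", sequence = seq1, modifications = "",
      mass_average = m1[["average"]], mass_monoisotopic = m1[["monoisotopic"]],
      printed_mass = row$printed_product1_mass,
      printed_int = row$printed_product1_int,
      printed_sequence = row$product1_seq, stringsAsFactors = FALSE
    )
    species[[3]] <- data.frame(
      species_id = sprintf("s%02d.p2", id), substrate_id = id,
      role = "cleavage_product_2", sequence = seq2, modifications = "",
      mass_average = m2[["average"]], mass_monoisotopic = m2[["monoisotopic"]],
      printed_mass = row$printed_product2_mass,
      printed_int = row$printed_product2_int,
      printed_sequence = row$product2_seq, stringsAsFactors = FALSE
    )
  } else if (row$enzyme_class == "kinase") {
    pm <- rbind(mods, data.frame(name = "phospho",
                                 position = as.character(row$phospho_position),
                                 stringsAsFactors = FALSE))
    m <- mass2(row$sequence, pm)
    species[[2]] <- data.frame(
      species_id = sprintf("s%02d.p1", id), substrate_id = id,
      role = "phosphorylated_product", sequence = row$sequence,
      modifications = mods_string(pm),
      mass_average = m[["average"]], mass_monoisotopic = m[["monoisotopic"]],
      printed_mass = row$printed_product1_mass,
      printed_int = row$printed_product1_int,
      printed_sequence = row$product1_seq, stringsAsFactors = FALSE
    )
  } else if (row$enzyme_class == "phosphatase") {
    keep <- !(mods$name == "phospho" &
                mods$position == as.character(row$phospho_position))
    if (all(keep)) {
      stop("phosphatase substrate id=", id,
           " carries no phospho at phospho_position")
    }
    dm <- mods[keep, , drop = FALSE]
    m <- mass2(row$sequence, dm)
    species[[2]] <- data.frame(
      species_id = sprintf("s%02d.p1", id), substrate_id = id,
      role = "dephosphorylated_product", sequence = row$sequence,
      modifications = mods_string(dm),
      mass_average = m[["average"]], mass_monoisotopic = m[["monoisotopic"]],
      printed_mass = row$printed_product1_mass,
      printed_int = row$printed_product1_int,
      printed_sequence = row$product1_seq, stringsAsFactors = FALSE
    )
  }

  out <- do.call(rbind, species)
  proton <- if (adduct == "M+H") residue_table$proton_mass else 0
  out$target_mz <- out$mass_average + proton
  out
}

#' Expected-species panel for a whole library
#'
#' @param library A `substrate_library`.
#' @inheritParams enumerate_expected_species
#' @return Data frame of class `expected_species_panel`: one row per
#'   measurable species (substrates and products).
#' @export
expected_species <- function(library, adduct = c("M+H", "neutral"),
                             residue_table = residue_mass_table()) {
  adduct <- match.arg(adduct)
  rows <- lapply(seq_len(nrow(library)), function(i) {
    enumerate_expected_species(library[i, ], adduct, residue_table)
  })
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  class(panel) <- c("expected_species_panel", class(panel))
  attr(panel, "adduct") <- adduct
  panel
}

#' Validate an expected-species panel
#'
#' Checks the panel against the two design rules for a MALDI substrate
#' panel: every targeted mass should sit above the low-mass matrix/tissue
#' background region, and no two targeted m/z values should be closer than
#' the resolvable interval separation (two extraction half-widths by
#' default, since two overlapping intervals cannot be distinguished).
#' Also reports substrates whose products do not differ in mass from the
#' substrate itself.
#'
#' @param panel An [expected_species()] panel (or a `substrate_library`,
#'   which is expanded first).
#' @param min_mass Minimum acceptable neutral mass in Da (default 600).
#' @param min_separation Minimum acceptable separation of target m/z values
#'   in Da (default `2 * 0.156`).
#' @return An object of class `panel_report` with elements `species`,
#'   `low_mass`, `collisions` (unordered pairs, sorted by mass then id) and
#'   `identity_violations`.
#' @export
validate_panel <- function(panel, min_mass = 600, min_separation = 0.312) {
  if (inherits(panel, "substrate_library")) panel <- expected_species(panel)
  stopifnot(min_separation >= 0)

  low <- panel[panel$mass_average < min_mass,
               c("species_id", "substrate_id", "role", "mass_average")]
  low <- low[order(low$mass_average, low$species_id), ]
  rownames(low) <- NULL

  # sorted sweep over target m/z; equivalent to the O(n^2) pairwise scan
  ord <- order(panel$target_mz, panel$species_id)
  mz <- panel$target_mz[ord]
  ids <- panel$species_id[ord]
  pairs <- list()
  n <- length(mz)
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      j <- i + 1L
      while (j <= n && (mz[j] - mz[i]) < min_separation) {
        a <- sort(c(ids[i], ids[j]))
        pairs[[length(pairs) + 1L]] <- data.frame(
          species_a = a[1], species_b = a[2],
          mz_a = mz[i], mz_b = mz[j],
          separation = mz[j] - mz[i], stringsAsFactors = FALSE
        )
        j <- j + 1L
      }
    }
  }
  collisions <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(species_a = character(), species_b = character(),
               mz_a = numeric(), mz_b = numeric(), separation = numeric(),
               stringsAsFactors = FALSE)
  collisions <- collisions[order(pmin(collisions$mz_a, collisions$mz_b),
                                 collisions$species_a), , drop = FALSE]
  rownames(collisions) <- NULL

  # substrate vs own products: conversion must change the mass
  ident <- list()
  for (sid in unique(panel$substrate_id)) {
    sub <- panel[panel$substrate_id == sid & panel$role == "substrate", ]
    prods <- panel[panel$substrate_id == sid & panel$role != "substrate", ]
    for (k in seq_len(nrow(prods))) {
      if (abs(prods$target_mz[k] - sub$target_mz) < min_separation) {
        ident[[length(ident) + 1L]] <- data.frame(
          substrate_id = sid, species_id = prods$species_id[k],
          separation = abs(prods$target_mz[k] - sub$target_mz),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  identity_violations <- if (length(ident) > 0) do.call(rbind, ident) else
    data.frame(substrate_id = integer(), species_id = character(),
               separation = numeric(), stringsAsFactors = FALSE)

  structure(
    list(species = panel, min_mass = min_mass, min_separation = min_separation,
         low_mass = low, collisions = collisions,
         identity_violations = identity_violations),
    class = "panel_report"
  )
}

#' @export
print.panel_report <- function(x, ...) {
  cat("Panel report:", nrow(x$species), "species\n")
  cat("  low-mass (<", x$min_mass, "Da):", nrow(x$low_mass), "\n")
  cat("  m/z collisions (<", x$min_separation, "Da):", nrow(x$collisions), "\n")
  if (nrow(x$collisions) > 0) {
    for (i in seq_len(nrow(x$collisions))) {
      cat(sprintf("    %s (%.4f) ~ %s (%.4f), d = %.4f\n",
                  x$collisions$species_a[i], x$collisions$mz_a[i],
                  x$collisions$species_b[i], x$collisions$mz_b[i],
                  x$collisions$separation[i]))
    }
  }
  cat("  substrate/product identity violations:",
      nrow(x$identity_violations), "\n")
  invisible(x)
}

#' Regression of computed masses against the published panel masses
#'
#' Compares the computed isotope-averaged mass of every species carrying a
#' published mass against that value, flags deviations beyond `tolerance`,
#' and annotates known irregularities in the published table rather than
#' dropping them: phosphorylated products printed exactly 79.90 Da above
#' their substrates (not the HPO3 average mass), a product sequence
#' inconsistent with its substrate, and the chemically tagged phosphatase
#' substrate whose printed substrate-product difference matches no phospho
#' delta.
#'
#' @param panel An [expected_species()] panel or a `substrate_library`.
#' @param tolerance Flag threshold on |computed - printed| in Da.
#' @return Data frame with one row per species with a published mass:
#'   computed and printed masses, `delta`, `flagged`, `sequence_mismatch`
#'   and a free-text `note`.
#' @export
regression_against_printed <- function(panel, tolerance = 0.05) {
  if (inherits(panel, "substrate_library")) panel <- expected_species(panel)
  out <- panel[, c("species_id", "substrate_id", "role", "sequence",
                   "printed_sequence", "mass_average", "printed_mass")]
  out$delta <- out$mass_average - out$printed_mass
  out$abs_delta <- abs(out$delta)
  out$flagged <- !is.na(out$abs_delta) & out$abs_delta > tolerance

  stripped <- vapply(out$printed_sequence, .strip_printed_seq, "")
  out$sequence_mismatch <- !is.na(stripped) & nzchar(stripped) &
    stripped != out$sequence

  out$note <- ""
  phos_delta <- modification_registry()
  phos_delta <- phos_delta$delta_average[phos_delta$name == "phospho"]
  for (i in seq_len(nrow(out))) {
    if (out$role[i] %in% c("phosphorylated_product", "dephosphorylated_product") &&
        !is.na(out$printed_mass[i])) {
      sub <- out[out$substrate_id == out$substrate_id[i] &
                   out$role == "substrate", ]
      printed_diff <- abs(sub$printed_mass - out$printed_mass[i])
      if (!is.na(printed_diff) && abs(printed_diff - phos_delta) > tolerance) {
        out$note[i] <- sprintf(
          "printed substrate-product difference %.2f != phospho delta %.2f",
          printed_diff, phos_delta)
      }
    }
    if (out$sequence_mismatch[i]) {
      out$note[i] <- paste0(out$note[i], if (nzchar(out$note[i])) "; ",
                            "printed sequence inconsistent with substrate; ",
                            "mass computed from substrate-derived sequence")
    }
  }
  rownames(out) <- NULL
  out
}
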