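#' Element mass table
#'
#' Standard atomic weights (isotope-abundance averaged) and monoisotopic
#' masses for the elements occurring in peptides and the supported chemical
#' modifications.  The average values are the classic IUPAC standard atomic
#' weights that underlie the ExPASy residue masses, so that masses computed
#' from elemental formulas are on the same scale as residue-sum masses.
#'
#' @return A data frame with columns `element`, `average`, `monoisotopic` (Da).
#' @export
element_mass_table <- function() {
  data.frame(
    element = c("C", "H", "N", "O", "P", "S"),
    average = c(12.0107, 1.00794, 14.0067, 15.9994, 30.973762, 32.065),
    monoisotopic = c(12.0, 1.0078250319, 14.0030740052, 15.9949146221,
                     30.97376151, 31.97207069),
    stringsAsFactors = FALSE
  )
}

#' Mass of an elemental formula
#'
#' @param formula Chemical formula such as `"HPO3"` or `"C12H8O4"`.  Element
#'   symbols followed by optional counts; no parentheses or charges.
#' @param scale `"average"` or `"monoisotopic"`.
#' @return Mass in Da.
#' @examples
#' formula_mass("H2O")
#' formula_mass("HPO3")
#' @export
formula_mass <- function(formula, scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  elems <- element_mass_table()
  masses <- stats::setNames(elems[[scale]], elems$element)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  total <- 0
  for (p in parts) {
    sym <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% names(masses)) stop("unknown element '", sym, "' in formula ", formula)
    total <- total + masses[[sym]] * n
  }
  total
}

# package-local cache for the residue table
.eaims_env <- new.env(parent = emptyenv())

#' Amino-acid residue mass table
#'
#' Average and monoisotopic residue masses (ExPASy values) for the 20
#' standard amino acids, plus the water and proton masses needed to turn
#' residue sums into neutral peptide masses and protonated m/z values.
#' The residue values are stored as package data
#' (`inst/extdata/residue_masses.tsv`) so an alternative table can be
#' swapped in, e.g. to probe small discrepancies in published masses.
#'
#' @param path Optional path to an alternative residue TSV with columns
#'   `residue`, `average`, `monoisotopic`.
#' @return An object of class `residue_mass_table`: a list with `residues`
#'   (data frame), `water_average`, `water_monoisotopic`, `proton_mass`.
#' @export
residue_mass_table <- function(path = NULL) {
  if (is.null(path) && !is.null(.eaims_env$residue_table)) {
    return(.eaims_env$residue_table)
  }
  if (is.null(path)) {
    path <- system.file("extdata", "residue_masses.tsv", package = "eaims",
                        mustWork = TRUE)
  }
  res <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "average", "monoisotopic") %in% names(res)))
  if (any(res$average <= 0) || any(res$monoisotopic <= 0)) {
    stop("residue masses must be strictly positive")
  }
  if (any(res$average < res$monoisotopic)) {
    stop("average residue mass below monoisotopic mass in table")
  }
  tab <- structure(
    list(
      residues = res,
      water_average = formula_mass("H2O", "average"),
      water_monoisotopic = formula_mass("H2O", "monoisotopic"),
      proton_mass = 1.00727646677
    ),
    class = "residue_mass_table"
  )
  if (is.null(.eaims_env$residue_table) &&
      basename(path) == "residue_masses.tsv") {
    .eaims_env$residue_table <- tab
  }
  tab
}

#' Registry of supported chemical modifications
#'
#' Mass deltas for the modifications used by the substrate library:
#' `phospho` (+HPO3 on Ser/Thr/Tyr), `MCA` ((7-methoxycoumarin-4-yl)acetyl
#' on the N-terminus, delta C12H8O4) and `DNP` (2,4-dinitrophenyl on a Lys
#' side chain, delta C6H2N2O4).  Deltas are computed from elemental
#' formulas via [formula_mass()].
#'
#' @return A data frame with one row per modification: `name`,
#'   `delta_average`, `delta_monoisotopic`, `attachment`.
#' @export
modification_registry <- function() {
  specs <- list(
    phospho = list(formula = "HPO3", attachment = "side-chain:STY"),
    MCA = list(formula = "C12H8O4", attachment = "N-terminus"),
    DNP = list(formula = "C6H2N2O4", attachment = "side-chain:K")
  )
  data.frame(
    name = names(specs),
    delta_average = vapply(specs, function(s) formula_mass(s$formula, "average"), 0),
    delta_monoisotopic = vapply(specs, function(s) formula_mass(s$formula, "monoisotopic"), 0),
    attachment = vapply(specs, function(s) s$attachment, ""),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Parse a modification string
#'
#' Modifications are written as semicolon-separated `name@position` tokens,
#' where position is a 1-based residue index, `nterm` or `cterm`
#' (e.g. `"MCA@nterm;phospho@5;DNP@8"`).
#'
#' @param x Modification string (may be `NA` or empty for none).
#' @return A data frame with columns `name` and `position` (character).
#' @export
parse_modifications <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(trimws(x))) {
    return(data.frame(name = character(), position = character(),
                      stringsAsFactors = FALSE))
  }
  toks <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  parts <- strsplit(toks, "@", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 2L
  if (any(bad)) stop("malformed modification token: ", toks[bad][1])
  data.frame(
    name = trimws(vapply(parts, `[[`, "", 1L)),
    position = trimws(vapply(parts, `[[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Neutral peptide mass
#'
#' Computes the neutral mass of a peptide as the sum of its residue masses
#' plus one water, plus the deltas of any attached modifications.
#'
#' @param sequence One-letter amino-acid string.
#' @param modifications `NULL`, a modification string (see
#'   [parse_modifications()]) or a data frame with columns `name`,
#'   `position`.
#' @param scale `"average"` (default; the scale of published panel masses)
#'   or `"monoisotopic"`.
#' @param table A [residue_mass_table()].
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("GTPGPQG")                     # 612.64
#' peptide_mass("RIRTQSFSLQE", "phospho@6") -
#'   peptide_mass("RIRTQSFSLQE")               # the HPO3 delta
#' @export
peptide_mass <- function(sequence, modifications = NULL,
                         scale = c("average", "monoisotopic"),
                         table = residue_mass_table()) {
  scale <- match.arg(scale)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- table$residues
  masses <- stats::setNames(res[[scale]], res$residue)
  letters_ <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- setdiff(letters_, names(masses))
  if (length(unknown) > 0) {
    stop("unknown residue letter(s) in sequence '", sequence, "': ",
         paste(unique(unknown), collapse = ", "))
  }
  total <- sum(masses[letters_]) +
    if (scale == "average") table$water_average else table$water_monoisotopic

  if (is.character(modifications)) modifications <- parse_modifications(modifications)
  if (!is.null(modifications) && nrow(modifications) > 0) {
    reg <- modification_registry()
    deltas <- stats::setNames(
      if (scale == "average") reg$delta_average else reg$delta_monoisotopic,
      reg$name
    )
    unknown_mod <- setdiff(modifications$name, names(deltas))
    if (length(unknown_mod) > 0) {
      stop("unknown modification name(s): ", paste(unknown_mod, collapse = ", "))
    }
    num_pos <- suppressWarnings(as.integer(modifications$position))
    in_seq <- is.na(num_pos) | (num_pos >= 1L & num_pos <= length(letters_))
    if (!all(in_seq)) {
      stop("modification position out of range for sequence '", sequence, "'")
    }
    total <- total + sum(deltas[modifications$name])
  }
  total
}
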