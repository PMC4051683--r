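# Chemical-formula and electron bookkeeping for membrane components.
#
# Electron-density profiles from reflectivity are only meaningful on an
# absolute e/A^3 scale when the total electron content of the unit cell is
# known.  This module supplies that budget: formula parsing, exact electron
# counts (sums of atomic numbers), IUPAC molar masses, peptide condensation
# arithmetic, and per-lipid electron budgets for mixed-composition leaflets.

# Atomic numbers and standard atomic masses (IUPAC, 3 decimals) for the
# elements that occur in phospholipids, sterols, hormones and peptides.
.elements <- data.frame(
  symbol = c("H", "C", "N", "O", "F", "Na", "Mg", "P", "S", "Cl",
             "K", "Ca", "Fe", "Zn", "Se", "Br", "I"),
  Z      = c(1L, 6L, 7L, 8L, 9L, 11L, 12L, 15L, 16L, 17L,
             19L, 20L, 26L, 30L, 34L, 35L, 53L),
  mass   = c(1.008, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305,
             30.974, 32.060, 35.450, 39.098, 40.078, 55.845, 65.380,
             78.971, 79.904, 126.904),
  stringsAsFactors = FALSE
)

#' Atomic number of an element symbol
#'
#' @param symbol Character vector of element symbols (case-sensitive,
#'   e.g. `"Na"`).
#' @return Integer vector of atomic numbers.
#' @export
atomic_number <- function(symbol) {
  i <- match(symbol, .elements$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol: ",
         paste(symbol[is.na(i)], collapse = ", "))
  }
  .elements$Z[i]
}

#' Parse a chemical formula string
#'
#' Parses Hill-style formula strings such as `"C36H72NO8P"` into a named
#' count vector.  Element symbols are one capital letter optionally
#' followed by one lowercase letter; a missing count means 1.  Repeated
#' symbols are summed.
#'
#' @param x A single formula string, or an already-parsed named numeric
#'   vector (returned unchanged after validation).
#' @return An object of class `chemical_formula`: a named integer vector of
#'   element counts.
#' @examples
#' chemical_formula("H2O")
#' chemical_formula("C27H46O")
#' @export
chemical_formula <- function(x) {
  if (inherits(x, "chemical_formula")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
  } else {
    if (!is.character(x) || length(x) != 1L || !nzchar(x))
      stop("formula must be a non-empty string or named count vector")
    m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
    tokens <- regmatches(x, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(x))
      stop("cannot parse formula string: '", x, "'")
    sym <- sub("[0-9]*$", "", tokens)
    n <- as.numeric(ifelse(grepl("[0-9]+$", tokens),
                           sub("^[A-Za-z]+", "", tokens), "1"))
    counts <- tapply(n, sym, sum)
    counts <- counts[order(names(counts))]
  }
  if (any(counts < 1) || any(counts != round(counts)))
    stop("element counts must be positive integers")
  atomic_number(names(counts))  # errors on unknown symbols
  structure(as.integer(counts), names = names(counts),
            class = "chemical_formula")
}

#' @export
print.chemical_formula <- function(x, ...) {
  cat("<chemical_formula> ",
      paste0(names(x), ifelse(x > 1, x, ""), collapse = ""),
      "  (", electrons_of_formula(x), " e-, ",
      sprintf("%.2f", molar_mass(x)), " g/mol)\n", sep = "")
  invisible(x)
}

#' Merge chemical formulas by summing element counts
#'
#' @param ... `chemical_formula` objects (or parseable inputs).
#' @return A `chemical_formula` with summed counts.
#' @export
merge_formulas <- function(...) {
  fs <- lapply(list(...), chemical_formula)
  all <- unlist(lapply(fs, function(f) stats::setNames(as.numeric(f), names(f))))
  counts <- tapply(all, names(all), sum)
  chemical_formula(counts[order(names(counts))])
}

#' Total electron count of a formula
#'
#' Sum over elements of atomic number times count; exact integer
#' arithmetic.
#'
#' @param formula A `chemical_formula` or formula string.
#' @return Integer electron count.
#' @examples
#' electrons_of_formula("H2O")        # 10
#' electrons_of_formula("C36H72NO8P") # 374 (DMPC)
#' @export
electrons_of_formula <- function(formula) {
  f <- chemical_formula(formula)
  as.integer(sum(atomic_number(names(f)) * as.integer(f)))
}

#' Molar mass of a formula
#'
#' @param formula A `chemical_formula` or formula string.
#' @return Molar mass in g/mol (IUPAC masses to 3 decimals).
#' @export
molar_mass <- function(formula) {
  f <- chemical_formula(formula)
  i <- match(names(f), .elements$symbol)
  sum(.elements$mass[i] * as.integer(f))
}

# Free (unbound) amino-acid formulas, one-letter codes.
.residues <- list(
  G = "C2H5NO2",  A = "C3H7NO2",   S = "C3H7NO3",   P = "C5H9NO2",
  V = "C5H11NO2", T = "C4H9NO3",   C = "C3H7NO2S",  L = "C6H13NO2",
  I = "C6H13NO2", N = "C4H8N2O3",  D = "C4H7NO4",   Q = "C5H10N2O3",
  K = "C6H14N2O2", E = "C5H9NO4",  M = "C5H11NO2S", H = "C6H9N3O2",
  F = "C9H11NO2", R = "C6H14N4O2", Y = "C9H11NO3",  W = "C11H12N2O2"
)

#' Free amino-acid formula for a one-letter code
#'
#' @param code Single canonical one-letter amino-acid code.
#' @return A `chemical_formula` of the free (unpolymerized) amino acid.
#' @export
residue_formula <- function(code) {
  f <- .residues[[code]]
  if (is.null(f)) stop("unknown amino-acid code: '", code, "'")
  chemical_formula(f)
}

#' Molecular formula of a peptide by condensation
#'
#' The peptide is treated as neutral with free N and C termini: the sum of
#' the free amino-acid formulas minus one water per peptide bond,
#' i.e. minus (n-1) H2O for an n-residue chain.  No protonation states or
#' modifications are modelled.
#'
#' @param sequence One-letter amino-acid string (canonical 20 codes).
#' @return A `chemical_formula`.
#' @examples
#' peptide_formula("G")            # free glycine, C2H5NO2
#' peptide_formula("GSNKGAIIGLM")  # C45H81N13O14S, 1060.3 g/mol
#' @export
peptide_formula <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  aa <- strsplit(sequence, "")[[1]]
  bad <- which(!aa %in% names(.residues))
  if (length(bad))
    stop("invalid amino-acid letter '", aa[bad[1]],
         "' at position ", bad[1])
  counts <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (a in aa) {
    f <- residue_formula(a)
    counts[names(f)] <- counts[names(f)] + as.integer(f)
  }
  n <- length(aa)
  counts["H"] <- counts["H"] - 2L * (n - 1L)
  counts["O"] <- counts["O"] - (n - 1L)
  counts <- counts[counts > 0]
  chemical_formula(counts[order(names(counts))])
}

#' Define a molecular species
#'
#' @param name Species name.
#' @param formula Formula string, `chemical_formula`, or peptide sequence
#'   when `sequence = TRUE`.
#' @param molar_mass_override Optional molar mass (g/mol) to report instead
#'   of the formula-derived value (e.g. when a salt form's mass is quoted
#'   for a species whose electron count is tabulated in protonated form).
#' @param printed_electrons Optional literature-tabulated electron count,
#'   retained for provenance when it conflicts with formula arithmetic.
#' @param sequence If `TRUE`, interpret `formula` as a one-letter peptide
#'   sequence.
#' @return An object of class `molecular_species` with fields `name`,
#'   `formula`, `electrons` (always formula-derived) and `molar_mass`.
#' @export
molecular_species <- function(name, formula, molar_mass_override = NULL,
                              printed_electrons = NULL, sequence = FALSE) {
  f <- if (isTRUE(sequence)) peptide_formula(formula) else chemical_formula(formula)
  structure(list(
    name = name,
    formula = f,
    electrons = electrons_of_formula(f),
    molar_mass = if (is.null(molar_mass_override)) molar_mass(f)
                 else molar_mass_override,
    printed_electrons = printed_electrons
  ), class = "molecular_species")
}

#' @export
print.molecular_species <- function(x, ...) {
  cat("<molecular_species> ", x$name, ": ",
      paste0(names(x$formula), ifelse(x$formula > 1, x$formula, ""),
             collapse = ""),
      ", ", x$electrons, " e-, ", sprintf("%.1f", x$molar_mass),
      " g/mol\n", sep = "")
  invisible(x)
}

#' Electron count of a species
#'
#' Returns the formula-derived electron count.  With
#' `source = "printed"` the literature-tabulated value is returned when
#' one was recorded; if it disagrees with formula arithmetic a warning is
#' emitted, since tabulated counts are occasionally inconsistent with the
#' tabulated formula/mass.
#'
#' @param species A `molecular_species`.
#' @param source `"formula"` (default) or `"printed"`.
#' @return Electron count.
#' @export
species_electrons <- function(species, source = c("formula", "printed")) {
  source <- match.arg(source)
  stopifnot(inherits(species, "molecular_species"))
  if (source == "printed" && !is.null(species$printed_electrons)) {
    if (species$printed_electrons != species$electrons)
      warning("tabulated electron count (", species$printed_electrons,
              ") for '", species$name,
              "' disagrees with its formula-derived value (",
              species$electrons, "); the formula value is authoritative",
              call. = FALSE)
    return(species$printed_electrons)
  }
  species$electrons
}

#' Built-in species registry
#'
#' The lipids, sterol, hormone, water, and the two amyloid-beta peptides
#' used throughout the package, with formula-derived electron counts.
#' Notes: DMPS is registered in its protonated form C34H66NO10P (372 e-),
#' which is the form consistent with the tabulated electron count; the
#' quoted molar mass 701.8 g/mol corresponds to the sodium salt and is
#' kept as an override.  The 11-residue amyloid-beta(25-35) fragment
#' carries a tabulated count of 678 e- that is inconsistent with its
#' formula C45H81N13O14S (570 e-, 1060.3 g/mol); the formula value is
#' used, and requesting the printed value warns.
#'
#' @return Named list of `molecular_species`.
#' @export
default_species <- function() {
  list(
    DMPC        = molecular_species("DMPC", "C36H72NO8P"),
    DMPS        = molecular_species("DMPS", "C34H66NO10P",
                                    molar_mass_override = 701.8),
    cholesterol = molecular_species("cholesterol", "C27H46O"),
    melatonin   = molecular_species("melatonin", "C13H16N2O2"),
    water       = molecular_species("water", "H2O"),
    abeta42     = molecular_species("abeta42",
                                    "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA",
                                    sequence = TRUE),
    abeta25_35  = molecular_species("abeta25_35", "GSNKGAIIGLM",
                                    sequence = TRUE,
                                    printed_electrons = 678)
  )
}

#' Membrane composition
#'
#' Describes the per-lipid stoichiometry of one leaflet: lipid mole
#' fractions (must sum to 1), additives as per-lipid mole ratios, bound
#' waters per lipid, the area per lipid and the lamellar spacing.
#'
#' @param lipids Named list: species name -> list(species, fraction), or
#'   more conveniently a list of `list(species = <molecular_species>,
#'   fraction = <x>)`.
#' @param additives Optional list of `list(species, ratio)` (per-lipid
#'   mole ratios).
#' @param waters_per_lipid Non-negative bound-water count per lipid.
#' @param area_per_lipid Area per lipid, Angstrom^2.
#' @param lamellar_spacing Lamellar repeat distance, Angstrom.
#' @return An object of class `membrane_composition`.
#' @export
membrane_composition <- function(lipids, additives = list(),
                                 waters_per_lipid = 0,
                                 area_per_lipid, lamellar_spacing) {
  if (length(lipids) == 0) stop("at least one lipid species is required")
  frac <- vapply(lipids, function(l) l$fraction, numeric(1))
  if (abs(sum(frac) - 1) > 1e-9)
    stop("lipid mole fractions must sum to 1 (got ",
         format(sum(frac), digits = 12), ")")
  stopifnot(waters_per_lipid >= 0, area_per_lipid > 0, lamellar_spacing > 0)
  structure(list(lipids = lipids, additives = additives,
                 waters_per_lipid = waters_per_lipid,
                 area_per_lipid = area_per_lipid,
                 lamellar_spacing = lamellar_spacing),
            class = "membrane_composition")
}

#' Per-lipid electron budget of one leaflet
#'
#' The expected number of electrons in one leaflet per lipid molecule:
#' the fraction-weighted lipid electrons, plus additives at their
#' per-lipid ratios, plus 10 electrons per bound water.  This is the
#' quantity that anchors the absolute scaling of electron-density
#' profiles.
#'
#' @param composition A `membrane_composition`.
#' @return Electrons per lipid (numeric).
#' @examples
#' sp <- default_species()
#' comp <- membrane_composition(
#'   lipids = list(list(species = sp$DMPC, fraction = 0.97),
#'                 list(species = sp$DMPS, fraction = 0.03)),
#'   waters_per_lipid = 7, area_per_lipid = 40.95, lamellar_spacing = 55.07)
#' leaflet_electron_budget(comp)  # 443.94
#' @export
leaflet_electron_budget <- function(composition) {
  stopifnot(inherits(composition, "membrane_composition"))
  lip <- sum(vapply(composition$lipids,
                    function(l) l$fraction * species_electrons(l$species),
                    numeric(1)))
  add <- if (length(composition$additives))
    sum(vapply(composition$additives,
               function(a) a$ratio * species_electrons(a$species),
               numeric(1))) else 0
  lip + add + composition$waters_per_lipid * 10
}
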