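# Standard atomic weights (IUPAC 2021, rounded); enough for the organic
# bookkeeping done here. Sulfur is present for molar mass only -- it never
# receives a valence (sulfate is treated as an explicit redox couple).
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  P = 30.974, S = 32.06, Na = 22.990, K = 39.098,
  Ca = 40.078, Mg = 24.305, Cl = 35.45, Fe = 55.845
)

#' Default valence convention for degree-of-reduction bookkeeping
#'
#' The convention that sets the reference states CO2, H2O and NH3 to a
#' degree of reduction of zero: C = +4, H = +1, O = -2, N = -3 (ammonia
#' reference for nitrogen). Under this convention the biomass formula
#' C4H7O1.5N carries 17 electron equivalents per mole. Sulfur is
#' deliberately absent: sulfate is handled as a terminal electron acceptor
#' via [redox_couple()], not through a degree of reduction.
#'
#' @return Named numeric vector of valences.
#' @export
#' @examples
#' default_valences()
default_valences <- function() {
  c(C = 4, H = 1, O = -2, N = -3)
}

#' Elemental formula
#'
#' Constructs an elemental formula from a Hill-like string with decimal
#' subscripts (e.g. `"C4H7O1.5N"`) or from a named numeric vector of
#' element counts. Fractional counts are allowed so that per-C-mole
#' biomass formulas can be represented exactly.
#'
#' @param x A formula string such as `"C12H22O11"`, or a named numeric
#'   vector like `c(C = 4, H = 7, O = 1.5, N = 1)`.
#' @param name Optional text label; defaults to the string form.
#' @return An object of class `elemental_formula`: a list with `elements`
#'   (named numeric, all counts >= 0) and `name`.
#' @export
#' @examples
#' elemental_formula("C4H7O1.5N", name = "biomass")
#' elemental_formula(c(C = 2, H = 4, O = 2), name = "acetate")
elemental_formula <- function(x, name = NULL) {
  if (inherits(x, "elemental_formula")) {
    if (!is.null(name)) x$name <- name
    return(x)
  }
  if (is.character(x)) {
    elements <- parse_formula(x)
    if (is.null(name)) name <- x
  } else if (is.numeric(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("numeric formula input must be a fully named vector", call. = FALSE)
    }
    elements <- x
    if (is.null(name)) name <- paste0(names(x), ifelse(x == 1, "", x), collapse = "")
  } else {
    stop("cannot interpret formula input of class ", class(x)[1], call. = FALSE)
  }
  if (length(elements) == 0L) stop("formula has no elements", call. = FALSE)
  if (any(elements < 0)) stop("element counts must be non-negative", call. = FALSE)
  structure(list(elements = elements, name = name), class = "elemental_formula")
}

# Parse a Hill-like formula string with decimal subscripts.
parse_formula <- function(string) {
  stopifnot(is.character(string), length(string) == 1L)
  s <- gsub("[[:space:]]", "", string)
  if (!nzchar(s)) stop("empty formula string", call. = FALSE)
  pattern <- "([A-Z][a-z]?)([0-9]*\\.?[0-9]*)"
  matches <- gregexpr(pattern, s, perl = TRUE)[[1]]
  consumed <- sum(attr(matches, "match.length"))
  if (consumed != nchar(s)) {
    stop("cannot parse formula string: '", string, "'", call. = FALSE)
  }
  parts <- regmatches(s, gregexpr(pattern, s, perl = TRUE))[[1]]
  symbols <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  counts <- sub("^[A-Z][a-z]?", "", parts)
  counts <- ifelse(counts == "", 1, as.numeric(counts))
  out <- numeric(0)
  for (i in seq_along(symbols)) {
    sym <- symbols[i]
    out[sym] <- (if (sym %in% names(out)) out[[sym]] else 0) + counts[i]
  }
  out
}

#' @export
print.elemental_formula <- function(x, ...) {
  counts <- x$elements
  cat("<elemental_formula> ", x$name, ": ",
      paste0(names(counts), ifelse(counts == 1, "", counts), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Moles of carbon per mole of compound
#'
#' @param formula An [elemental_formula()] (or string coerced to one).
#' @return Carbon count per mole; 0 for carbon-free species.
#' @export
#' @examples
#' carbon_per_mol("C12H22O11") # 12
carbon_per_mol <- function(formula) {
  f <- elemental_formula(formula)
  if ("C" %in% names(f$elements)) unname(f$elements[["C"]]) else 0
}

#' Molar mass of an elemental formula
#'
#' Standard atomic-mass sum. A [biomass_formula()] overrides this with its
#' minerals-inclusive molar mass (the dry-weight convention used for cell
#' material).
#'
#' @param formula An [elemental_formula()], [biomass_formula()] or string.
#' @param ... Unused.
#' @return g/mol.
#' @export
#' @examples
#' molar_mass("H2")            # 2.016
#' molar_mass(biomass_formula()) # 104 (includes minerals)
molar_mass <- function(formula, ...) UseMethod("molar_mass")

#' @export
molar_mass.default <- function(formula, ...) {
  f <- elemental_formula(formula)
  syms <- names(f$elements)
  unknown <- setdiff(syms, names(.ATOMIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(f$elements * .ATOMIC_MASS[syms])
}

#' @export
molar_mass.biomass_formula <- function(formula, ...) {
  formula$molar_mass_with_minerals
}

#' Degree of reduction (electron equivalents per mole)
#'
#' The generalized degree of reduction: the electron equivalents released
#' by complete oxidation of one mole of compound to the reference states
#' CO2, H2O and NH3, computed as the valence-weighted sum of element
#' counts. Under the default convention, gamma(CO2) = 0 and
#' gamma(C4H7O1.5N biomass) = 17.
#'
#' @param formula An [elemental_formula()] or string.
#' @param valences Named vector mapping element symbol to valence;
#'   defaults to [default_valences()].
#' @return Electron equivalents per mole (may be zero or negative).
#' @export
#' @examples
#' degree_of_reduction("C4H7O1.5N") # 17
#' degree_of_reduction("C12H22O11") # 48 (cellobiose)
#' degree_of_reduction("CO2")       # 0
degree_of_reduction <- function(formula, valences = default_valences()) {
  f <- elemental_formula(formula)
  syms <- names(f$elements)
  missing <- setdiff(syms, names(valences))
  if (length(missing)) {
    stop("no valence defined for element(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sum(f$elements * valences[syms])
}

#' Biomass formula with minerals-inclusive mass
#'
#' Cell material is carried with two parallel conventions: carbon
#' accounting uses the organic formula (default C4H7O1.5N, 4 C/mol and 17
#' electron equivalents/mol), while mass accounting uses the
#' minerals-inclusive dry-weight molar mass (default 104 g/mol). The
#' energy carried per electron equivalent is configurable (default -0.3 V;
#' literature values for this formula range to about -0.37 V).
#'
#' @param formula Organic formula (string or [elemental_formula()]).
#' @param molar_mass_with_minerals Dry-weight g/mol including mineral ash.
#' @param electron_equivalents_per_mol Electron equivalents released on
#'   complete oxidation of one mole; must equal the degree of reduction of
#'   `formula` under `valences`.
#' @param energy_per_equivalent Volts per electron equivalent.
#' @param valences Valence convention used for the consistency check.
#' @return A `biomass_formula` object (subclass of `elemental_formula`).
#' @export
#' @examples
#' b <- biomass_formula()
#' molar_mass(b)          # 104
#' degree_of_reduction(b) # 17
biomass_formula <- function(formula = "C4H7O1.5N",
                            molar_mass_with_minerals = 104,
                            electron_equivalents_per_mol = NULL,
                            energy_per_equivalent = -0.3,
                            valences = default_valences()) {
  f <- elemental_formula(formula, name = "biomass")
  organic_mass <- molar_mass.default(f)
  if (molar_mass_with_minerals < organic_mass) {
    stop("minerals-inclusive molar mass (", molar_mass_with_minerals,
         ") below the organic formula mass (", round(organic_mass, 1), ")",
         call. = FALSE)
  }
  gamma <- degree_of_reduction(f, valences)
  if (is.null(electron_equivalents_per_mol)) {
    electron_equivalents_per_mol <- gamma
  } else if (abs(electron_equivalents_per_mol - gamma) > 1e-9) {
    stop("electron_equivalents_per_mol (", electron_equivalents_per_mol,
         ") inconsistent with degree of reduction (", gamma, ")", call. = FALSE)
  }
  structure(
    list(
      elements = f$elements,
      name = f$name,
      molar_mass_with_minerals = molar_mass_with_minerals,
      electron_equivalents_per_mol = electron_equivalents_per_mol,
      energy_per_equivalent = energy_per_equivalent
    ),
    class = c("biomass_formula", "elemental_formula")
  )
}

#' Terminal electron-acceptor couple
#'
#' Encodes an acceptor -> reduced-product couple by the electron
#' equivalents it accepts per mole, for species whose redox bookkeeping is
#' not done through a degree of reduction (e.g. sulfate -> sulfide, 8;
#' fumarate -> succinate, 2).
#'
#' @param name Couple label, e.g. `"sulfate/sulfide"`.
#' @param electrons_accepted_per_mol Positive electron equivalents per mole
#'   of acceptor reduced.
#' @return A `redox_couple` object.
#' @export
#' @examples
#' redox_couple("sulfate/sulfide", 8)
redox_couple <- function(name, electrons_accepted_per_mol) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(electrons_accepted_per_mol) ||
      electrons_accepted_per_mol <= 0) {
    stop("electrons_accepted_per_mol must be > 0", call. = FALSE)
  }
  structure(list(name = name,
                 electrons_accepted_per_mol = electrons_accepted_per_mol),
            class = "redox_couple")
}

#' Default redox couples for the tri-culture system
#'
#' @return Named list of [redox_couple()] objects: sulfate reduction to
#'   sulfide (8 e-/mol) and fumarate reduction to succinate (2 e-/mol).
#' @export
default_redox_couples <- function() {
  list(
    sulfate = redox_couple("sulfate/sulfide", 8),
    fumarate = redox_couple("fumarate/succinate", 2)
  )
}

#' Check element and electron balance of a reaction
#'
#' Given signed stoichiometric coefficients (products positive, reactants
#' negative), reports the net per-element sums and the net electron
#' equivalents. A balanced redox reaction reports zero for every element
#' and for electrons, within tolerance.
#'
#' @param stoichiometry Named numeric vector: names are formula strings (or
#'   registry compound names), values are signed coefficients.
#' @param valences Valence convention for the electron sum.
#' @param tol Absolute tolerance in coefficient units (default 1e-9).
#' @return A list with `element_imbalance` (named numeric),
#'   `carbon_imbalance`, `electron_imbalance`, and logical `balanced`.
#' @export
#' @examples
#' # cellobiose hydrolysis conserves carbon
#' check_reaction_balance(c(C12H22O11 = -1, H2O = -1, C6H12O6 = 2))$carbon_imbalance
check_reaction_balance <- function(stoichiometry,
                                   valences = default_valences(),
                                   tol = 1e-9) {
  if (is.null(names(stoichiometry)) || length(stoichiometry) < 2L) {
    stop("stoichiometry must be a named vector with >= 2 species", call. = FALSE)
  }
  if (all(stoichiometry >= 0) || all(stoichiometry <= 0)) {
    stop("need at least one reactant (negative) and one product (positive)",
         call. = FALSE)
  }
  formulas <- lapply(names(stoichiometry), resolve_formula)
  element_net <- numeric(0)
  electron_net <- 0
  for (i in seq_along(formulas)) {
    f <- formulas[[i]]
    coef <- stoichiometry[[i]]
    for (sym in names(f$elements)) {
      element_net[sym] <- (if (sym %in% names(element_net)) element_net[[sym]] else 0) +
        coef * f$elements[[sym]]
    }
    electron_net <- electron_net + coef * degree_of_reduction(f, valences)
  }
  carbon <- if ("C" %in% names(element_net)) element_net[["C"]] else 0
  list(
    element_imbalance = element_net,
    carbon_imbalance = carbon,
    electron_imbalance = electron_net,
    balanced = all(abs(element_net) <= tol) && abs(electron_net) <= tol
  )
}

# Resolve a name to an elemental_formula: registry compound name first,
# then as a raw formula string.
resolve_formula <- function(name) {
  reg <- compound_registry()
  hit <- match(tolower(name), tolower(reg$name))
  if (!is.na(hit)) {
    return(elemental_formula(reg$formula[hit], name = reg$name[hit]))
  }
  elemental_formula(name)
}

#' Compound registry for the tri-culture system
#'
#' The metabolites tracked by the pipeline with their elemental formulas
#' (acid forms throughout, matching millimolar bookkeeping at pH ~7), a
#' charge note, and their role in the trophic network. Shipped as a
#' plain-text table under `inst/extdata/compounds.tsv`.
#'
#' @return data.frame with columns `name`, `formula`, `charge_note`, `role`.
#' @export
#' @examples
#' head(compound_registry())
compound_registry <- function() {
  path <- system.file("extdata", "compounds.tsv", package = "triflux")
  if (!nzchar(path)) path <- "inst/extdata/compounds.tsv"
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Degree of reduction for a registry compound
#'
#' Convenience lookup: resolves a compound name through the registry and
#' returns its degree of reduction, or `NA` for species (sulfate, sulfide)
#' that the convention deliberately leaves without one.
#'
#' @param name Compound name or formula string.
#' @param valences Valence convention.
#' @return Electron equivalents per mole, or `NA_real_`.
#' @export
compound_gamma <- function(name, valences = default_valences()) {
  f <- resolve_formula(name)
  if (any(!names(f$elements) %in% names(valences))) return(NA_real_)
  degree_of_reduction(f, valences)
}
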