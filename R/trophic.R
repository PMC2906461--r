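#' Species roles in the trophic network
#'
#' Declarative description of who eats what: the fermenter consumes
#' cellobiose and excretes acetate, CO2 and reduced fermentation products
#' (H2/ethanol); the sulfate reducer consumes those reduced products with
#' sulfate as terminal acceptor (no CO2 -- incomplete TCA cycle); the
#' fumarate respirer oxidizes acetate with fumarate as acceptor, producing
#' succinate, malate and CO2.
#'
#' @return Named list of role definitions.
#' @export
default_species_roles <- function() {
  list(
    "C. cellulolyticum" = list(
      donors = "cellobiose",
      acceptors = character(0),
      products = c("acetate", "co2", "hydrogen", "ethanol"),
      carbon_source = "cellobiose",
      produces_co2 = TRUE
    ),
    "D. vulgaris" = list(
      donors = c("hydrogen", "ethanol"),
      acceptors = "sulfate",
      products = "sulfide",
      carbon_source = "acetate",
      produces_co2 = FALSE  # incomplete TCA cycle
    ),
    "G. sulfurreducens" = list(
      donors = "acetate",
      acceptors = "fumarate",
      products = c("succinate", "malate", "co2"),
      carbon_source = "acetate",
      produces_co2 = TRUE
    )
  )
}

#' Allocation parameters for community flux splitting
#'
#' The measured supernatant constrains community totals but not every
#' inter-species transfer; these parameters close the system.
#'
#' @param geobacter_acetate_uptake Moles of acetate drawn by the fumarate
#'   respirer per mole of cellobiose consumed (default 0.45).
#' @param geobacter_acetate_oxidized Moles of that acetate fully oxidized
#'   to CO2 (default 0.3; the remainder is carbon assimilated).
#' @param h2_fraction_of_donor_pool Fraction (by electron equivalents) of
#'   the unresolved electron-donor pool feeding sulfate reduction carried
#'   as H2, the rest as ethanol. The true ratio is not identifiable from
#'   supernatant data; default 0.5 is an explicit coin-flip, labelled
#'   unresolved in every report.
#' @param co2_per_supernatant_acetate CO2 released by the fermenter per
#'   mole of acetate left in the supernatant (default 1, the 1:1
#'   acetate:CO2 stoichiometry of cellobiose fermentation applied to the
#'   net acetate).
#' @return A `flux_splits` object.
#' @export
flux_splits <- function(geobacter_acetate_uptake = 0.45,
                        geobacter_acetate_oxidized = 0.3,
                        h2_fraction_of_donor_pool = 0.5,
                        co2_per_supernatant_acetate = 1) {
  if (geobacter_acetate_oxidized > geobacter_acetate_uptake) {
    stop("oxidized acetate cannot exceed uptake", call. = FALSE)
  }
  if (h2_fraction_of_donor_pool < 0 || h2_fraction_of_donor_pool > 1) {
    stop("h2_fraction_of_donor_pool must be in [0, 1]", call. = FALSE)
  }
  structure(list(geobacter_acetate_uptake = geobacter_acetate_uptake,
                 geobacter_acetate_oxidized = geobacter_acetate_oxidized,
                 h2_fraction_of_donor_pool = h2_fraction_of_donor_pool,
                 co2_per_supernatant_acetate = co2_per_supernatant_acetate),
            class = "flux_splits")
}

#' Allocate community fluxes to species per mole of cellobiose
#'
#' Normalizes measured steady-state consumption/production to moles per
#' mole of cellobiose consumed and assigns each flux to the species
#' responsible: cellobiose and fermentation products to the fermenter,
#' sulfate turnover to the sulfate reducer, the fumarate--succinate--malate
#' pool and its acetate draw to the fumarate respirer. The electron-donor
#' pool feeding sulfate reduction (hydrogen, interspecies electron
#' transfer, or ethanol -- not distinguishable from supernatant data) is
#' carried as an unresolved electron-equivalent quantity split between H2
#' and ethanol by `splits$h2_fraction_of_donor_pool`.
#'
#' @param state A [chemostat_state()] with residual mM for cellobiose,
#'   acetate, fumarate, succinate, malate and sulfate (absent compounds
#'   are treated as zero).
#' @param config A [reactor_config()] supplying feed concentrations.
#' @param roles Species role definitions (default
#'   [default_species_roles()]).
#' @param splits A [flux_splits()] object.
#' @return A `flux_table`: data.frame (`species`, `compound`,
#'   `mol_per_mol_cellobiose`) with attributes `basis_mM` (cellobiose
#'   consumed, mM), `donor_pool_eeq` (unresolved electron equivalents per
#'   mole cellobiose) and `unresolved_pool` flag.
#' @export
#' @examples
#' st <- chemostat_state(
#'   residual = c(cellobiose = 0, acetate = 5.93, fumarate = 0,
#'                succinate = 3.586, malate = 0.044, sulfate = 1.9),
#'   od600 = 0.4)
#' ft <- allocate_fluxes(st, reactor_config())
#' subset(community_fluxes(ft), compound == "acetate") # ~2.7 mol/mol
allocate_fluxes <- function(state, config,
                            roles = default_species_roles(),
                            splits = flux_splits()) {
  feed <- function(cmpd) if (cmpd %in% names(config$feed)) config$feed[[cmpd]] else 0
  resid <- function(cmpd) if (cmpd %in% names(state$residual)) state$residual[[cmpd]] else 0

  cb_consumed <- feed("cellobiose") - resid("cellobiose")
  if (cb_consumed <= 0) stop("no cellobiose consumption in state", call. = FALSE)
  per_mol <- function(mM) mM / cb_consumed

  acetate_net <- per_mol(resid("acetate") - feed("acetate"))
  fumarate_in <- per_mol(feed("fumarate") - resid("fumarate"))
  succinate_out <- per_mol(resid("succinate") - feed("succinate"))
  malate_out <- per_mol(resid("malate") - feed("malate"))
  sulfate_red <- per_mol(feed("sulfate") - resid("sulfate"))

  gs_uptake <- splits$geobacter_acetate_uptake
  gs_oxidized <- splits$geobacter_acetate_oxidized
  gs_co2 <- 2 * gs_oxidized                    # C2 -> 2 C1
  cc_acetate <- acetate_net + gs_uptake        # fermenter gross production
  cc_co2 <- splits$co2_per_supernatant_acetate * acetate_net

  # unresolved donor pool: electron equivalents required by sulfate reduction
  pool_eeq <- 8 * sulfate_red
  h2_mol <- pool_eeq * splits$h2_fraction_of_donor_pool / 2
  etoh_mol <- pool_eeq * (1 - splits$h2_fraction_of_donor_pool) / 12

  # donor-capacity check: fermenter electron products vs cellobiose supply
  cc_e_products <- 8 * cc_acetate + pool_eeq
  if (cc_e_products > degree_of_reduction("C12H22O11") + 1e-9) {
    warning("acceptor flux exceeds fermenter donor capacity ",
            "(implied electron recovery > 100%); reported as-is", call. = FALSE)
  }

  sp <- names(roles)
  rows <- rbind(
    data.frame(species = sp[1], compound = c("cellobiose", "acetate", "co2",
                                             "hydrogen", "ethanol"),
               mol_per_mol_cellobiose = c(-1, cc_acetate, cc_co2,
                                          h2_mol, etoh_mol)),
    data.frame(species = sp[2], compound = c("sulfate", "sulfide",
                                             "hydrogen", "ethanol"),
               mol_per_mol_cellobiose = c(-sulfate_red, sulfate_red,
                                          -h2_mol, -etoh_mol)),
    data.frame(species = sp[3], compound = c("acetate", "fumarate",
                                             "succinate", "malate", "co2"),
               mol_per_mol_cellobiose = c(-gs_uptake, -fumarate_in,
                                          succinate_out, malate_out, gs_co2))
  )
  structure(rows,
            basis_mM = cb_consumed,
            donor_pool_eeq = pool_eeq,
            unresolved_pool = pool_eeq > 0,
            splits = splits,
            class = c("flux_table", "data.frame"))
}

#' Community-level net fluxes from a flux table
#'
#' @param fluxes A `flux_table` from [allocate_fluxes()].
#' @param drop_zero Drop compounds whose net flux is ~0 (cross-fed species
#'   cancel at community level).
#' @return data.frame `compound`, `mol_per_mol_cellobiose`.
#' @export
community_fluxes <- function(fluxes, drop_zero = TRUE) {
  agg <- stats::aggregate(mol_per_mol_cellobiose ~ compound,
                          data = fluxes, FUN = sum)
  if (drop_zero) agg <- agg[abs(agg$mol_per_mol_cellobiose) > 1e-12, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# Split a flux vector into inputs (|consumed|) and products.
.flux_in_out <- function(flux_df) {
  x <- flux_df$mol_per_mol_cellobiose
  names(x) <- flux_df$compound
  list(inputs = -x[x < 0], products = x[x > 0])
}

# Biomass in mol per mol cellobiose from mg/L and the basis concentration.
.biomass_mol_per_mol <- function(biomass_mg_L, biomass, basis_mM) {
  (biomass_mg_L / molar_mass(biomass)) / basis_mM
}

#' Carbon recovery percentage
#'
#' 100 x (carbon in products + biomass) / (carbon in consumed substrates).
#' Biomass is counted at 4 C per 104 g dry weight (organic formula for
#' carbon, minerals-inclusive mass for grams).
#'
#' @param fluxes A `flux_table` (community totals are used), or any
#'   data.frame with `compound` and `mol_per_mol_cellobiose`.
#' @param biomass A [biomass_formula()].
#' @param biomass_mg_L Community (or species) biomass, mg dw/L; 0 to
#'   exclude cell mass.
#' @param basis_mM Cellobiose consumed (mM); taken from the flux table
#'   attribute when present.
#' @return Percent.
#' @export
carbon_recovery <- function(fluxes, biomass = biomass_formula(),
                            biomass_mg_L = 0, basis_mM = NULL) {
  if (nrow(fluxes) == 0L) stop("empty flux table", call. = FALSE)
  if (is.null(basis_mM)) basis_mM <- attr(fluxes, "basis_mM")
  net <- if (inherits(fluxes, "flux_table")) community_fluxes(fluxes) else fluxes
  io <- .flux_in_out(net)
  c_in <- sum(io$inputs * vapply(names(io$inputs), carbon_per_mol_registry, 0))
  if (c_in <= 0) stop("zero carbon input", call. = FALSE)
  c_out <- sum(io$products * vapply(names(io$products), carbon_per_mol_registry, 0))
  if (biomass_mg_L > 0) {
    if (is.null(basis_mM)) stop("basis_mM required when counting biomass", call. = FALSE)
    c_out <- c_out + .biomass_mol_per_mol(biomass_mg_L, biomass, basis_mM) *
      carbon_per_mol(biomass)
  }
  100 * c_out / c_in
}

# registry-aware carbon lookup (names like "co2", "sulfate" resolve there)
carbon_per_mol_registry <- function(name) carbon_per_mol(resolve_formula(name))

#' Electron recovery percentage
#'
#' 100 x (electron equivalents in products + biomass) / (electron
#' equivalents in consumed substrates). Degrees of reduction follow the
#' default valence convention; sulfate enters the denominator at zero (a
#' pure terminal acceptor) and its reduced product sulfide enters the
#' numerator at the couple's 8 e-/mol. Biomass carries 17 e-/mol. Values
#' above 100% are reported as-is -- they are the signature of unmeasured
#' donor pools, not an error.
#'
#' @inheritParams carbon_recovery
#' @param couples Named list of [redox_couple()]s (default
#'   [default_redox_couples()]); the sulfate couple prices sulfide.
#' @param valences Valence convention.
#' @return Percent.
#' @export
electron_recovery <- function(fluxes, biomass = biomass_formula(),
                              biomass_mg_L = 0, basis_mM = NULL,
                              couples = default_redox_couples(),
                              valences = default_valences()) {
  if (nrow(fluxes) == 0L) stop("empty flux table", call. = FALSE)
  if (is.null(basis_mM)) basis_mM <- attr(fluxes, "basis_mM")
  net <- if (inherits(fluxes, "flux_table")) community_fluxes(fluxes) else fluxes
  io <- .flux_in_out(net)
  gamma_of <- function(name) {
    g <- compound_gamma(name, valences)
    if (!is.na(g)) return(g)
    if (tolower(name) == "sulfide" && "sulfate" %in% names(couples)) {
      return(couples$sulfate$electrons_accepted_per_mol)
    }
    0 # terminal acceptors (sulfate) carry no degree of reduction
  }
  e_in <- sum(io$inputs * vapply(names(io$inputs), gamma_of, 0))
  if (e_in <= 0) stop("zero electron input", call. = FALSE)
  e_out <- sum(io$products * vapply(names(io$products), gamma_of, 0))
  if (biomass_mg_L > 0) {
    if (is.null(basis_mM)) stop("basis_mM required when counting biomass", call. = FALSE)
    e_out <- e_out + .biomass_mol_per_mol(biomass_mg_L, biomass, basis_mM) *
      biomass$electron_equivalents_per_mol
  }
  100 * e_out / e_in
}

#' Fraction of input energy left in digestible end products
#'
#' 100 x sum over digestible products of mol x gamma x weight, over the
#' same sum across consumed substrates. Digestible end products are the
#' reduced compounds whose electron equivalents remain available to
#' further trophic levels (acetate, succinate, ethanol, hydrogen; malate
#' included by default as a readily metabolized acid, excludable).
#' Biomass and sulfide are always excluded from the numerator. Weights
#' default to 1, giving a pure electron-equivalent fraction; per-compound
#' energy weights (volts) may be supplied but no canonical set is shipped.
#'
#' @inheritParams carbon_recovery
#' @param digestible Character vector of digestible compound names.
#' @param weights Named numeric per-compound energy weights; unnamed
#'   compounds get 1.
#' @param valences Valence convention.
#' @return Percent.
#' @export
digestible_energy_fraction <- function(fluxes,
                                       digestible = c("acetate", "succinate",
                                                      "ethanol", "hydrogen",
                                                      "malate"),
                                       weights = NULL,
                                       valences = default_valences()) {
  if (length(digestible) == 0L) stop("digestible set is empty", call. = FALSE)
  digestible <- setdiff(tolower(digestible), c("biomass", "sulfide"))
  net <- if (inherits(fluxes, "flux_table")) community_fluxes(fluxes) else fluxes
  io <- .flux_in_out(net)
  w <- function(name) {
    if (!is.null(weights) && name %in% names(weights)) weights[[name]] else 1
  }
  gma <- function(name) {
    g <- compound_gamma(name, valences)
    if (is.na(g)) 0 else g
  }
  denom <- sum(vapply(names(io$inputs),
                      function(n) io$inputs[[n]] * gma(n) * w(n), 0))
  if (denom <= 0) return(0)
  keep <- names(io$products)[tolower(names(io$products)) %in% digestible]
  numer <- sum(vapply(keep, function(n) io$products[[n]] * gma(n) * w(n), 0))
  100 * numer / denom
}

#' Partition community biomass among species
#'
#' Proportional allocation by cell counts, optionally weighted by relative
#' per-cell dry mass. The output always sums exactly to the input biomass.
#'
#' @param biomass_mg_L Community biomass, mg dw/L.
#' @param counts Named per-species cells/ml (>= 0, not all zero).
#' @param cell_mass_weights Relative per-cell mass weights (default equal).
#' @return Named mg/L vector summing to `biomass_mg_L`.
#' @export
#' @examples
#' partition_biomass(236, c(Cc = 4.6e8, Dv = 0.29e8, Gs = 0.36e8))
partition_biomass <- function(biomass_mg_L, counts, cell_mass_weights = NULL) {
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (sum(counts) == 0) stop("all counts are zero", call. = FALSE)
  if (is.null(cell_mass_weights)) {
    cell_mass_weights <- stats::setNames(rep(1, length(counts)), names(counts))
  }
  mass <- counts * cell_mass_weights[names(counts)]
  biomass_mg_L * mass / sum(mass)
}

#' Build the community balance report
#'
#' Assembles the community row and one row per species with the five
#' standard columns: cell counts (x 1e8/ml), biomass (mg/L), carbon
#' recovered (%), electrons recovered (%), and energy remaining in
#' digestible end products (%). Per-species recoveries use each species'
#' own sub-fluxes plus its biomass share; they inherit the unresolved
#' donor-pool assumption and are labelled accordingly.
#'
#' @param fluxes A `flux_table` from [allocate_fluxes()].
#' @param counts Named per-species cells/ml.
#' @param biomass_mg_L Community biomass, mg dw/L.
#' @param biomass A [biomass_formula()].
#' @param couples Redox couples for electron pricing.
#' @param digestible Digestible compound set.
#' @param energy_weights Optional per-compound energy weights.
#' @return A `balance_report`: data.frame with columns `group`,
#'   `cell_counts_1e8`, `biomass_mg_L`, `c_recovered_pct`,
#'   `e_recovered_pct`, `digestible_pct`, plus attributes `flags` and
#'   `basis_mM`. Percentages carry full precision; [print.balance_report()]
#'   rounds to integers for display.
#' @export
build_report <- function(fluxes, counts, biomass_mg_L,
                         biomass = biomass_formula(),
                         couples = default_redox_couples(),
                         digestible = c("acetate", "succinate", "ethanol",
                                        "hydrogen", "malate"),
                         energy_weights = NULL) {
  basis <- attr(fluxes, "basis_mM")
  shares <- partition_biomass(biomass_mg_L, counts)
  rows <- data.frame(
    group = "community",
    cell_counts_1e8 = sum(counts) / 1e8,
    biomass_mg_L = biomass_mg_L,
    c_recovered_pct = carbon_recovery(fluxes, biomass, biomass_mg_L, basis),
    e_recovered_pct = electron_recovery(fluxes, biomass, biomass_mg_L, basis,
                                        couples),
    digestible_pct = digestible_energy_fraction(fluxes, digestible,
                                                energy_weights),
    stringsAsFactors = FALSE
  )
  for (sp in unique(fluxes$species)) {
    sub <- fluxes[fluxes$species == sp, , drop = FALSE]
    sub_net <- stats::aggregate(mol_per_mol_cellobiose ~ compound,
                                data = sub, FUN = sum)
    share <- if (sp %in% names(shares)) shares[[sp]] else 0
    cr <- tryCatch(carbon_recovery(sub_net, biomass, share, basis),
                   error = function(e) NA_real_)
    er <- tryCatch(electron_recovery(sub_net, biomass, share, basis, couples),
                   error = function(e) NA_real_)
    de <- digestible_energy_fraction(sub_net, digestible, energy_weights)
    rows <- rbind(rows, data.frame(
      group = sp,
      cell_counts_1e8 = if (sp %in% names(counts)) counts[[sp]] / 1e8 else NA_real_,
      biomass_mg_L = share,
      c_recovered_pct = cr, e_recovered_pct = er, digestible_pct = de,
      stringsAsFactors = FALSE
    ))
  }
  flags <- character(0)
  if (isTRUE(attr(fluxes, "unresolved_pool"))) {
    flags <- c(flags, paste0(
      "unresolved_donor_pool: ", round(attr(fluxes, "donor_pool_eeq"), 2),
      " e-eq/mol cellobiose to sulfate reduction could be hydrogen, ",
      "interspecies electron transfer, or ethanol"))
  }
  flags <- c(flags, "species biomass = exact proportional allocation of community biomass")
  structure(rows, flags = flags, basis_mM = basis,
            class = c("balance_report", "data.frame"))
}

#' @export
print.balance_report <- function(x, ...) {
  shown <- as.data.frame(x)
  shown$cell_counts_1e8 <- round(shown$cell_counts_1e8, 2)
  shown$biomass_mg_L <- round(shown$biomass_mg_L, 1)
  for (col in c("c_recovered_pct", "e_recovered_pct", "digestible_pct")) {
    shown[[col]] <- round(shown[[col]])
  }
  cat("Community carbon/electron balance (basis: ",
      signif(attr(x, "basis_mM"), 3), " mM cellobiose consumed)\n", sep = "")
  print(shown, row.names = FALSE)
  for (f in attr(x, "flags")) cat("* ", f, "\n", sep = "")
  invisible(x)
}

#' Write a balance report to CSV
#'
#' Columns mirror the printed report; units are embedded in the header
#' names. Flags are written as trailing comment lines. The write is atomic
#' (temp file + rename).
#'
#' @param report A `balance_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(as.data.frame(report), tmp, row.names = FALSE)
  con <- file(tmp, open = "a")
  for (f in attr(report, "flags")) writeLines(paste("#", f), con)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a balance report written by [write_report()]
#'
#' @param path CSV path.
#' @return A `balance_report` (flags restored from comment lines).
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  flags <- sub("^# ", "", grep("^#", lines, value = TRUE))
  df <- utils::read.csv(textConnection(grep("^#", lines, value = TRUE,
                                            invert = TRUE)),
                        stringsAsFactors = FALSE)
  structure(df, flags = flags, class = c("balance_report", "data.frame"))
}
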