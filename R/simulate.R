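#' Simulated species: kinetics plus growth-linked stoichiometry
#'
#' A species is described by Monod kinetics (multiplicative over its
#' limiting substrates) and a growth-linked overall reaction expressed in
#' moles per mole of biomass formed (biomass itself implied at +1, with
#' 4 C and 17 electron equivalents per mole and 104 g dry weight with
#' minerals). The reaction must be carbon- and electron-balanced; the
#' simulator refuses unbalanced sets.
#'
#' @param name Species label.
#' @param mu_max Maximum specific growth rate, 1/h; a species persists in
#'   the chemostat only if `mu_max` exceeds the dilution rate.
#' @param ks Named vector of Monod half-saturation constants, mM.
#' @param stoich Named vector, mol per mol biomass formed (negative =
#'   consumed). Biomass excluded.
#' @param inhibition Optional product-inhibition term: list with
#'   `compound`, `threshold_mM`, `hill`; growth is scaled by
#'   1/(1 + (S/threshold)^hill).
#' @return A `sim_species` object.
#' @export
sim_species <- function(name, mu_max, ks, stoich, inhibition = NULL) {
  if (mu_max < 0) stop("mu_max must be >= 0", call. = FALSE)
  if (any(ks <= 0)) stop("half-saturation constants must be positive", call. = FALSE)
  if (!all(names(ks) %in% names(stoich))) {
    stop("every Monod substrate needs a stoichiometry entry", call. = FALSE)
  }
  structure(list(name = name, mu_max = mu_max, ks = ks, stoich = stoich,
                 inhibition = inhibition),
            class = "sim_species")
}

# carbon and electron content of a growth-linked reaction, biomass included
.reaction_imbalance <- function(stoich, biomass = biomass_formula()) {
  gma <- function(name) {
    g <- compound_gamma(name)
    if (!is.na(g)) return(g)
    if (tolower(name) == "sulfide") return(8)
    0 # sulfate: terminal acceptor, no degree of reduction
  }
  cnet <- sum(vapply(names(stoich),
                     function(n) stoich[[n]] * carbon_per_mol_registry(n), 0)) +
    carbon_per_mol(biomass)
  enet <- sum(vapply(names(stoich), function(n) stoich[[n]] * gma(n), 0)) +
    biomass$electron_equivalents_per_mol
  c(carbon = cnet, electron = enet)
}

#' Balanced fermenter stoichiometry
#'
#' Constructs the cellobiose fermentation reaction per mole of biomass by
#' closing carbon with equimolar acetate/CO2 and electrons with H2, so the
#' reaction is balanced for any parameter choice.
#'
#' @param cellobiose_per_biomass mol cellobiose consumed per mol biomass.
#' @param ethanol_per_biomass mol ethanol produced per mol biomass.
#' @return Named stoichiometry vector (mol per mol biomass).
#' @export
fermenter_stoichiometry <- function(cellobiose_per_biomass = 1.075,
                                    ethanol_per_biomass = 0.054) {
  q <- cellobiose_per_biomass
  e <- ethanol_per_biomass
  acetate <- (12 * q - 4 - 2 * e) / 3
  h2 <- (48 * q - 17 - 8 * acetate - 12 * e) / 2
  if (acetate < 0 || h2 < 0) {
    stop("fermenter parameters leave no room for acetate/H2 products",
         call. = FALSE)
  }
  c(cellobiose = -q, acetate = acetate, co2 = acetate,
    ethanol = e, hydrogen = h2)
}

#' Balanced sulfate-reducer stoichiometry
#'
#' Hydrogen and ethanol serve as electron donors (ethanol is incompletely
#' oxidized to acetate, 4 e-/mol), acetate provides cell carbon, and
#' sulfate is reduced to sulfide at 8 e-/mol. Electrons close exactly:
#' 4 x ethanol + 2 x H2 = 8 x sulfate + 17 (biomass) - 16 (acetate carbon
#' electrons).
#'
#' @param sulfate_per_biomass mol sulfate reduced per mol biomass (the
#'   inverse growth yield; sulfate reducers grow lean).
#' @param ethanol_e_fraction Fraction of donor electron equivalents taken
#'   from ethanol rather than H2.
#' @return Named stoichiometry vector.
#' @export
srb_stoichiometry <- function(sulfate_per_biomass = 25,
                              ethanol_e_fraction = 0.02) {
  s <- sulfate_per_biomass
  n_eeq <- 8 * s + 1 # donor electrons: sulfide + biomass deficit over acetate
  etoh <- ethanol_e_fraction * n_eeq / 4
  h2 <- (1 - ethanol_e_fraction) * n_eeq / 2
  c(acetate = etoh - 2, ethanol = -etoh, hydrogen = -h2,
    sulfate = -s, sulfide = s)
}

#' Balanced fumarate-respirer stoichiometry
#'
#' Acetate is the electron donor and carbon source; fumarate is reduced to
#' succinate (2 e-/mol) with a small hydration branch to malate. Carbon
#' and electrons close by construction: 0.25 acetate oxidized to CO2 per
#' fumarate reduced, 2.125 acetate per biomass.
#'
#' @param fumarate_per_biomass mol fumarate consumed per mol biomass.
#' @param malate_fraction Fraction of consumed fumarate diverted to malate.
#' @return Named stoichiometry vector.
#' @export
geobacter_stoichiometry <- function(fumarate_per_biomass = 31.25,
                                    malate_fraction = 0.012) {
  f_tot <- fumarate_per_biomass
  mal <- malate_fraction * f_tot
  f_red <- f_tot - mal
  acetate <- -(0.25 * f_red + 2 + 1 / 8)
  co2 <- 0.5 * f_red + 0.25
  c(acetate = acetate, fumarate = -f_tot, succinate = f_red,
    malate = mal, co2 = co2)
}

#' Default three-species simulation preset
#'
#' Kinetic constants are not measurable from steady-state supernatant data
#' and are calibrated once so that the deterministic steady state
#' resembles the tri-culture: cellobiose nearly exhausted, fumarate
#' removed completely, residual sulfate left over, dissolved H2 in the
#' sub-micromolar range, and ~230 mg/L biomass dominated by the fermenter.
#' The fermenter carries succinate product inhibition with a 10 mM
#' threshold.
#'
#' @return Named list of three [sim_species()].
#' @export
default_sim_species <- function() {
  list(
    "C. cellulolyticum" = sim_species(
      "C. cellulolyticum", mu_max = 0.15,
      ks = c(cellobiose = 0.1),
      stoich = fermenter_stoichiometry(),
      inhibition = list(compound = "succinate", threshold_mM = 10, hill = 4)
    ),
    "D. vulgaris" = sim_species(
      "D. vulgaris", mu_max = 0.1,
      ks = c(hydrogen = 5e-4, sulfate = 0.2, acetate = 0.05),
      stoich = srb_stoichiometry()
    ),
    "G. sulfurreducens" = sim_species(
      "G. sulfurreducens", mu_max = 0.1,
      ks = c(acetate = 0.05, fumarate = 0.05),
      stoich = geobacter_stoichiometry()
    )
  )
}

#' Simulate a chemostat community
#'
#' Deterministic mass- and electron-conserving ODE model:
#' dS/dt = D (S_in - S) + sum_i nu_i,S mu_i X_i / M_X and
#' dX_i/dt = (mu_i - D) X_i, with multiplicative Monod kinetics, optional
#' product inhibition, and first-order gas stripping of dissolved H2 at
#' the headspace exchange rate. Cumulative carbon/electron inflow and
#' outflow are integrated alongside the state so conservation can be
#' verified to solver tolerance. The reaction set is validated before the
#' run; an unbalanced species is refused.
#'
#' @param config A [reactor_config()].
#' @param species List of [sim_species()] (default the calibrated
#'   tri-culture preset).
#' @param duration_days Days simulated.
#' @param seed Retained for manifest reproducibility; the solution is
#'   deterministic and does not consume randomness.
#' @param inoculum_mg_L Named initial biomass, mg dw/L.
#' @param initial_conc Optional named initial concentrations, mM;
#'   compounds not named start at their feed concentration.
#' @param events Optional list of events, each
#'   `list(type = "mu_factor", species =, factor =, start_day =, end_day =)`;
#'   used for upset scenarios.
#' @param dt_out_days Output grid spacing, days.
#' @param rtol,atol Solver tolerances.
#' @param gas_stripping Named first-order stripping constants, 1/h
#'   (default: H2 at the headspace turnover rate).
#' @param solver `"ros23"` (stiff-capable, default) or `"rk45"`.
#' @return A `sim_result`: list with `times_days`, `conc` (matrix, mM),
#'   `biomass` (matrix, mg/L), `od600`, `conservation` (closure summary),
#'   and the inputs.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_chemostat(duration_days = 2)
#' tail(sim$conc[, "cellobiose"], 1)
#' }
simulate_chemostat <- function(config = reactor_config(),
                               species = default_sim_species(),
                               duration_days = 20,
                               seed = 1L,
                               inoculum_mg_L = NULL,
                               initial_conc = NULL,
                               events = NULL,
                               dt_out_days = 0.25,
                               rtol = 1e-8, atol = 1e-10,
                               gas_stripping = NULL,
                               solver = c("ros23", "rk45")) {
  solver <- match.arg(solver)
  biomass <- biomass_formula()
  for (sp in species) {
    imb <- .reaction_imbalance(sp$stoich, biomass)
    if (any(abs(imb) > 1e-6)) {
      stop("unbalanced reaction for ", sp$name, ": carbon ",
           signif(imb["carbon"], 3), ", electrons ",
           signif(imb["electron"], 3), "; refusing to run", call. = FALSE)
    }
  }
  if (is.null(inoculum_mg_L)) {
    inoculum_mg_L <- stats::setNames(
      c(16, 1, 1.2)[seq_along(species)],
      vapply(species, `[[`, "", "name"))
  }
  if (any(inoculum_mg_L < 0)) {
    stop("inoculum must be non-negative", call. = FALSE)
  }

  compounds <- unique(unlist(lapply(species, function(sp) names(sp$stoich))))
  nc <- length(compounds)
  ns <- length(species)
  sp_names <- vapply(species, `[[`, "", "name")
  D <- dilution_rate(config)
  feed <- stats::setNames(numeric(nc), compounds)
  shared <- intersect(names(config$feed), compounds)
  feed[shared] <- config$feed[shared]
  if (is.null(gas_stripping)) {
    gas_stripping <- c(hydrogen = config$headspace_gas_flow * 60 /
                         config$working_volume)
  }
  strip <- stats::setNames(numeric(nc), compounds)
  shared_g <- intersect(names(gas_stripping), compounds)
  strip[shared_g] <- gas_stripping[shared_g]

  cvec <- vapply(compounds, carbon_per_mol_registry, 0)
  gma <- function(name) {
    g <- compound_gamma(name)
    if (!is.na(g)) return(g)
    if (tolower(name) == "sulfide") return(8)
    0
  }
  evec <- vapply(compounds, gma, 0)
  m_x <- molar_mass(biomass) # mg/mmol
  bio_c <- carbon_per_mol(biomass)
  bio_e <- biomass$electron_equivalents_per_mol

  nu <- matrix(0, ns, nc, dimnames = list(sp_names, compounds))
  for (i in seq_len(ns)) nu[i, names(species[[i]]$stoich)] <- species[[i]]$stoich

  mu_factor_at <- function(t_hours) {
    fac <- stats::setNames(rep(1, ns), sp_names)
    for (ev in events) {
      if (ev$type != "mu_factor") stop("unknown event type '", ev$type, "'", call. = FALSE)
      if (t_hours >= ev$start_day * 24 && t_hours < ev$end_day * 24) {
        fac[ev$species] <- fac[ev$species] * ev$factor
      }
    }
    fac
  }

  deriv <- function(t, y) {
    conc <- pmax(y[seq_len(nc)], 0)
    x <- pmax(y[nc + seq_len(ns)], 0)
    fac <- mu_factor_at(t)
    mu <- numeric(ns)
    for (i in seq_len(ns)) {
      sp <- species[[i]]
      m <- sp$mu_max * fac[i]
      for (s in names(sp$ks)) {
        m <- m * conc[s] / (sp$ks[[s]] + conc[s])
      }
      if (!is.null(sp$inhibition)) {
        inh <- sp$inhibition
        m <- m / (1 + (conc[inh$compound] / inh$threshold_mM)^inh$hill)
      }
      mu[i] <- m
    }
    r_bio <- mu * x / m_x # mmol biomass/L/h
    dconc <- D * (feed - conc) + drop(crossprod(nu, r_bio)) - strip * conc
    dx <- (mu - D) * x
    out_c <- D * (sum(conc * cvec) + sum(x) / m_x * bio_c)
    out_e <- D * (sum(conc * evec) + sum(x) / m_x * bio_e) +
      sum(strip * conc * evec)
    c(dconc, dx, D * sum(feed * cvec), out_c, D * sum(feed * evec), out_e)
  }

  conc0 <- feed
  if (!is.null(initial_conc)) {
    shared0 <- intersect(names(initial_conc), compounds)
    conc0[shared0] <- initial_conc[shared0]
  }
  y0 <- c(conc0, inoculum_mg_L[sp_names], 0, 0, 0, 0)
  names(y0) <- c(compounds, sp_names, "cumC_in", "cumC_out",
                 "cumE_in", "cumE_out")
  times_days <- seq(0, duration_days, by = dt_out_days)
  integrate <- if (solver == "ros23") ode_ros23 else ode_rk45
  sol <- integrate(deriv, y0, times_days * 24, rtol = rtol, atol = atol)

  conc <- sol[, seq_len(nc), drop = FALSE]
  xmat <- sol[, nc + seq_len(ns), drop = FALSE]
  total_x <- rowSums(xmat)
  # conservation closure at the final time point
  c0 <- sum(y0[seq_len(nc)] * cvec) + sum(inoculum_mg_L) / m_x * bio_c
  e0 <- sum(y0[seq_len(nc)] * evec) + sum(inoculum_mg_L) / m_x * bio_e
  nT <- nrow(sol)
  cT <- sum(pmax(conc[nT, ], 0) * cvec) + total_x[nT] / m_x * bio_c
  eT <- sum(pmax(conc[nT, ], 0) * evec) + total_x[nT] / m_x * bio_e
  conservation <- list(
    carbon_closure = unname((cT + sol[nT, "cumC_out"]) /
                              (c0 + sol[nT, "cumC_in"])),
    electron_closure = unname((eT + sol[nT, "cumE_out"]) /
                                (e0 + sol[nT, "cumE_in"]))
  )
  structure(list(times_days = times_days, conc = conc, biomass = xmat,
                 od600 = total_x / biomass_calibration()$mg_dw_per_liter_per_od,
                 conservation = conservation, config = config,
                 species = species, seed = seed, events = events),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  nT <- length(x$times_days)
  cat("<sim_result> ", x$times_days[nT], " days, ",
      ncol(x$conc), " compounds, ", ncol(x$biomass), " species\n", sep = "")
  cat("  final OD600 ", round(x$od600[nT], 3), "; carbon closure ",
      signif(x$conservation$carbon_closure, 6), "; electron closure ",
      signif(x$conservation$electron_closure, 6), "\n", sep = "")
  invisible(x)
}

#' Tri-culture scenario container
#'
#' @param config Reactor configuration.
#' @param species Simulated species list.
#' @param duration_days Days.
#' @param events Event list (see [simulate_chemostat()]).
#' @return A `sim_scenario` list.
#' @export
tri_culture_scenario <- function(config = reactor_config(),
                                 species = default_sim_species(),
                                 duration_days = 20,
                                 events = NULL) {
  structure(list(config = config, species = species,
                 duration_days = duration_days, events = events),
            class = "sim_scenario")
}

#' Derive an upset scenario from a base scenario
#'
#' `"sporulation"` silences the fermenter for a window (residual
#' cellobiose climbs back toward the feed, bounded by it);
#' `"high_fumarate"` raises the feed fumarate, which drives succinate
#' toward the fermenter's inhibition threshold.
#'
#' @param base A [tri_culture_scenario()].
#' @param trigger `"sporulation"` or `"high_fumarate"`.
#' @param window_days Length-2 start/end (days) of the sporulation window.
#' @param fumarate_feed_mM Elevated feed fumarate for the high-fumarate
#'   trigger.
#' @return A modified `sim_scenario`.
#' @export
make_upset_scenario <- function(base,
                                trigger = c("sporulation", "high_fumarate"),
                                window_days = c(6, 9),
                                fumarate_feed_mM = 10) {
  trigger <- match.arg(trigger)
  out <- base
  if (trigger == "sporulation") {
    fermenter <- vapply(base$species, `[[`, "", "name")[1]
    out$events <- c(base$events, list(list(
      type = "mu_factor", species = fermenter, factor = 0,
      start_day = window_days[1], end_day = window_days[2])))
  } else {
    out$config$feed[["fumarate"]] <- fumarate_feed_mM
  }
  out
}

#' Run a scenario
#'
#' @param scenario A [tri_culture_scenario()].
#' @param ... Passed to [simulate_chemostat()].
#' @return A `sim_result`.
#' @export
run_scenario <- function(scenario, ...) {
  simulate_chemostat(config = scenario$config, species = scenario$species,
                     duration_days = scenario$duration_days,
                     events = scenario$events, ...)
}

#' Measurement noise model
#'
#' @param conc_sd_rel Relative sd of concentration measurements.
#' @param conc_sd_abs_mM Absolute sd floor, mM.
#' @param od_sd Absolute sd of OD600 readings.
#' @param cq_sd Sd of technical-replicate Cq, cycles.
#' @param bio_cv Lognormal coefficient of variation between biological
#'   replicates (sampling/extraction variability).
#' @param detection_limits_mM Named left-censoring limits (default:
#'   dissolved H2 at 0.3 uM).
#' @return A `noise_model` object.
#' @export
noise_model <- function(conc_sd_rel = 0.05, conc_sd_abs_mM = 0.02,
                        od_sd = 0.01, cq_sd = 0.1, bio_cv = 0.05,
                        detection_limits_mM = c(hydrogen = 3e-4)) {
  vals <- c(conc_sd_rel, conc_sd_abs_mM, od_sd, cq_sd, bio_cv)
  if (any(vals < 0)) stop("noise sds must be >= 0", call. = FALSE)
  structure(list(conc_sd_rel = conc_sd_rel, conc_sd_abs_mM = conc_sd_abs_mM,
                 od_sd = od_sd, cq_sd = cq_sd, bio_cv = bio_cv,
                 detection_limits_mM = detection_limits_mM),
            class = "noise_model")
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate observation tables from a simulation
#'
#' Produces the three tables the analysis pipeline consumes, with seeded
#' measurement noise and left-censoring at detection limits:
#' a metabolite table (daily HPLC-style concentrations), an OD table, and
#' a long-format qPCR plate (3 biological x 3 technical replicates per
#' species and day) generated through a synthetic standard curve. With an
#' all-zero noise model the observations reproduce the simulation exactly
#' (censoring still applies). Output is bit-identical for a fixed seed.
#'
#' @param sim A `sim_result`.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param days Days at which samples are taken (default: integer days).
#' @param curve_slope,curve_intercept Synthetic standard-curve parameters
#'   shared by all species (slope -3.3219 = perfect doubling).
#' @param calibration [biomass_calibration()] for biomass -> cells.
#' @param assays Named list of [species_assay()]s keyed by species name.
#' @return List with `metabolites` (day, compound, concentration_mM,
#'   censored), `od` (day, od600), `plate` (plate CSV dialect), `curves`
#'   (per-species `standard_curve` objects fitted to a noiseless synthetic
#'   dilution series), and `truth` (noise-free per-species cells/ml).
#' @export
observe <- function(sim, noise = noise_model(), seed = 1L,
                    days = NULL,
                    curve_slope = -1 / log10(2),
                    curve_intercept = 38,
                    calibration = biomass_calibration(),
                    assays = NULL) {
  if (is.null(days)) days <- unique(floor(sim$times_days))
  days <- days[days >= min(sim$times_days) & days <= max(sim$times_days)]
  idx <- vapply(days, function(d) which.min(abs(sim$times_days - d)), 1L)
  if (is.null(assays)) {
    d <- default_species_assays()
    assays <- stats::setNames(d, vapply(d, `[[`, "", "species"))
  }
  slope <- curve_slope

  with_seed(seed, {
    compounds <- colnames(sim$conc)
    met <- do.call(rbind, lapply(seq_along(days), function(k) {
      truth <- pmax(sim$conc[idx[k], ], 0)
      sd <- noise$conc_sd_rel * truth + noise$conc_sd_abs_mM
      obs <- pmax(truth + stats::rnorm(length(truth), 0, sd), 0)
      lim <- noise$detection_limits_mM[compounds]
      lim[is.na(lim)] <- 0
      censored <- obs < lim
      obs[censored] <- lim[censored]
      data.frame(day = days[k], compound = compounds,
                 concentration_mM = unname(obs),
                 censored = unname(censored), row.names = NULL)
    }))

    od <- data.frame(
      day = days,
      od600 = pmax(sim$od600[idx] + stats::rnorm(length(days), 0, noise$od_sd), 0)
    )

    per_cell_mg <- calibration$mg_dw_per_liter_per_od /
      calibration$cells_per_ml_at_reference
    sp_names <- colnames(sim$biomass)
    plate <- list()
    truth_cells <- list()
    for (sp in sp_names) {
      assay <- assays[[sp]]
      if (is.null(assay)) stop("no assay for simulated species '", sp, "'", call. = FALSE)
      for (k in seq_along(days)) {
        cells_ml <- max(sim$biomass[idx[k], sp], 0) / per_cell_mg / 1000
        truth_cells[[length(truth_cells) + 1L]] <- data.frame(
          day = days[k], species = sp, cells_per_ml = cells_ml)
        for (b in 1:3) {
          bio_factor <- if (noise$bio_cv > 0) {
            stats::rlnorm(1, -log(1 + noise$bio_cv^2) / 2,
                          sqrt(log(1 + noise$bio_cv^2)))
          } else 1
          copies_rxn <- cells_ml * bio_factor * assay$rrn_copies_per_genome *
            10 / (100 / 0.5) # 10 ml culture -> 100 ul eluate, 0.5 ul/rxn
          cq_true <- curve_intercept + slope * log10(max(copies_rxn, 1))
          for (tech in 1:3) {
            plate[[length(plate) + 1L]] <- data.frame(
              sample = sprintf("d%02g_b%d", days[k], b),
              day = days[k], species = sp,
              cq = min(max(cq_true + stats::rnorm(1, 0, noise$cq_sd), 1), 45),
              bio_rep = b, tech_rep = tech)
          }
        }
      }
    }
    plate <- do.call(rbind, plate)

    curves <- lapply(sp_names, function(sp) {
      copies <- 10^(2:8)
      fit_standard_curve(copies, curve_intercept + slope * log10(copies))
    })
    names(curves) <- sp_names

    list(metabolites = met, od = od, plate = plate, curves = curves,
         truth = do.call(rbind, truth_cells))
  })
}
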