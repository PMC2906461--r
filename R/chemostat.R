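#' Reactor configuration
#'
#' Operating parameters of the continuous-culture vessel. Defaults are the
#' tri-culture preset: 650 ml working volume fed at 0.34 ml/min (dilution
#' rate ~0.03 1/h), 49 ml/min nitrogen sparge, 30 degrees C, and a feed of
#' 2.2 mM cellobiose, 4.9 mM fumarate, 8 mM sulfate and 5 mM bicarbonate.
#' The mass-balance sections of the analysis historically quote a 640 ml
#' culture; use `preset = "balance"` for that variant.
#'
#' @param working_volume ml.
#' @param feed_flow ml/min.
#' @param headspace_gas_flow ml/min nitrogen.
#' @param temperature Degrees C.
#' @param feed Named numeric vector, compound -> mM.
#' @param preset `"reactor"` (650 ml, default) or `"balance"` (640 ml).
#' @return A `reactor_config` object.
#' @export
#' @examples
#' cfg <- reactor_config()
#' dilution_rate(cfg)
reactor_config <- function(working_volume = NULL,
                           feed_flow = 0.34,
                           headspace_gas_flow = 49,
                           temperature = 30,
                           feed = c(cellobiose = 2.2, fumarate = 4.9,
                                    sulfate = 8, NaHCO3 = 5),
                           preset = c("reactor", "balance")) {
  preset <- match.arg(preset)
  if (is.null(working_volume)) {
    working_volume <- if (preset == "balance") 640 else 650
  }
  if (working_volume <= 0) stop("working_volume must be positive", call. = FALSE)
  if (feed_flow < 0) stop("feed_flow must be non-negative", call. = FALSE)
  if (headspace_gas_flow <= 0 || temperature <= 0) {
    stop("gas flow and temperature must be positive", call. = FALSE)
  }
  if (any(feed < 0)) stop("feed concentrations must be non-negative", call. = FALSE)
  cfg <- structure(
    list(working_volume = working_volume, feed_flow = feed_flow,
         headspace_gas_flow = headspace_gas_flow, temperature = temperature,
         feed = feed, preset = preset),
    class = "reactor_config"
  )
  if (dilution_rate(cfg) >= 1) {
    stop("dilution rate >= 1/h fails the chemostat sanity bound", call. = FALSE)
  }
  cfg
}

#' @export
print.reactor_config <- function(x, ...) {
  cat("<reactor_config> ", x$working_volume, " ml, ", x$feed_flow,
      " ml/min (D = ", signif(dilution_rate(x), 3), " 1/h), ",
      x$temperature, " C\n", sep = "")
  cat("  feed (mM): ", paste(names(x$feed), x$feed, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Dilution rate of a chemostat
#'
#' D = feed flow / working volume, converted to 1/h. At steady state D
#' equals the specific growth rate of every persisting species.
#'
#' @param config A [reactor_config()].
#' @return 1/h.
#' @export
#' @examples
#' dilution_rate(reactor_config()) # ~0.031, i.e. 0.03 at two decimals
dilution_rate <- function(config) {
  if (config$working_volume <= 0) stop("working volume must be > 0", call. = FALSE)
  config$feed_flow * 60 / config$working_volume
}

#' Chemostat state at (or near) steady state
#'
#' @param residual Named numeric vector, compound -> residual mM in the
#'   culture supernatant.
#' @param od600 Optical density at 600 nm.
#' @param gas_headspace Named numeric vector, gas -> partial pressure (atm)
#'   in the headspace. Optional.
#' @param pH Culture pH; values outside 6.5--8 trigger a warning (the
#'   tri-culture holds 7.0--7.2 unassisted).
#' @return A `chemostat_state` object.
#' @export
chemostat_state <- function(residual, od600, gas_headspace = numeric(0),
                            pH = 7.1) {
  if (any(residual < 0)) stop("residual concentrations must be >= 0", call. = FALSE)
  if (od600 < 0) stop("od600 must be >= 0", call. = FALSE)
  if (pH < 6.5 || pH > 8) {
    warning("pH ", pH, " outside the stable 6.5-8 band", call. = FALSE)
  }
  structure(list(residual = residual, od600 = od600,
                 gas_headspace = gas_headspace, pH = pH),
            class = "chemostat_state")
}

#' Biomass calibration constants
#'
#' Conversion factors anchored on a fermenter monoculture: an OD600 of 1.0
#' corresponds to 590 mg dry weight per litre and 1.3e9 cells per ml.
#'
#' @param mg_dw_per_liter_per_od mg dw/L per OD600 unit.
#' @param cells_per_ml_at_reference cells/ml at OD600 = 1.0.
#' @return A `biomass_calibration` object.
#' @export
biomass_calibration <- function(mg_dw_per_liter_per_od = 590,
                                cells_per_ml_at_reference = 1.3e9) {
  if (mg_dw_per_liter_per_od <= 0 || cells_per_ml_at_reference <= 0) {
    stop("calibration constants must be positive", call. = FALSE)
  }
  structure(list(mg_dw_per_liter_per_od = mg_dw_per_liter_per_od,
                 cells_per_ml_at_reference = cells_per_ml_at_reference),
            class = "biomass_calibration")
}

#' Convert OD600 to dry-weight biomass
#'
#' Linear conversion: OD 0.4 -> 236 mg dw/L under the default calibration.
#'
#' @param od600 Optical density (>= 0).
#' @param calibration A [biomass_calibration()].
#' @return mg dw/L.
#' @export
od_to_biomass <- function(od600, calibration = biomass_calibration()) {
  if (any(od600 < 0)) stop("od600 must be >= 0", call. = FALSE)
  od600 * calibration$mg_dw_per_liter_per_od
}

#' Convert dry-weight biomass to cell density
#'
#' Uses the per-cell dry mass implied by the calibration
#' (590 mg/L over 1.3e9 cells/ml at OD 1). By pure proportionality
#' 236 mg/L gives 5.2e8 cells/ml; note that rounded figures of 5.25e8
#' circulate for the same culture.
#'
#' @param biomass mg dw/L (>= 0).
#' @param calibration A [biomass_calibration()].
#' @return cells/ml.
#' @export
biomass_to_cell_density <- function(biomass,
                                    calibration = biomass_calibration()) {
  if (any(biomass < 0)) stop("biomass must be >= 0", call. = FALSE)
  biomass / calibration$mg_dw_per_liter_per_od *
    calibration$cells_per_ml_at_reference
}

#' Steady-state volumetric flux of a compound
#'
#' At steady state the net biological flux of a compound balances the
#' hydraulic flux: D * (residual - feed). Negative values mean net
#' consumption; set `consumption_positive = TRUE` to flip the sign
#' convention.
#'
#' @param config A [reactor_config()].
#' @param state A [chemostat_state()].
#' @param compound Compound name present in the feed and/or residual table.
#' @param consumption_positive Flip sign so consumption is positive.
#' @return mmol/L/h.
#' @export
#' @examples
#' st <- chemostat_state(residual = c(cellobiose = 0.1), od600 = 0.4)
#' steady_state_flux(reactor_config(), st, "cellobiose",
#'                   consumption_positive = TRUE)
steady_state_flux <- function(config, state, compound,
                              consumption_positive = FALSE) {
  feed <- if (compound %in% names(config$feed)) config$feed[[compound]] else 0
  resid <- if (compound %in% names(state$residual)) state$residual[[compound]] else 0
  if (!compound %in% names(config$feed) &&
      !compound %in% names(state$residual)) {
    stop("compound '", compound, "' in neither feed nor residual table",
         call. = FALSE)
  }
  flux <- dilution_rate(config) * (resid - feed)
  if (consumption_positive) -flux else flux
}

# Henry's-law solubility constants at 25 C, mol/L/atm, with van't Hoff
# temperature coefficients (K). Compiled from standard solubility tables;
# overridable via the `constants` argument of dissolved_gas().
.HENRY_CONSTANTS <- data.frame(
  gas = c("co2", "h2", "h2s", "n2"),
  kh_298 = c(0.034, 7.8e-4, 0.102, 6.5e-4),
  vant_hoff = c(2400, 500, 2100, 1300)
)

#' Dissolved gas concentration from partial pressure
#'
#' Henry's-law solubility with van't Hoff temperature correction. For CO2
#' a modified calculation accounts for the chemical reactivity of the gas:
#' total dissolved inorganic carbon is CO2(aq) * (1 + 10^(pH - pKa1)),
#' using only the first carbonate equilibrium (pKa1 = 6.35), adequate
#' below pH 7.2 where carbonate is negligible.
#'
#' @param partial_pressure atm.
#' @param gas One of `"co2"`, `"h2"`, `"h2s"`, `"n2"` (or any gas present
#'   in `constants`).
#' @param temperature Degrees C.
#' @param pH Culture pH (used for CO2 speciation only).
#' @param pKa1 First carbonate pKa.
#' @param speciate For CO2, include the bicarbonate pool (default TRUE).
#' @param detection_limit_mM Optional detection limit; concentrations below
#'   it are flagged as left-censored via the `"censored"` attribute.
#' @param constants Henry-constant table (columns `gas`, `kh_298`,
#'   `vant_hoff`) to override the compiled defaults.
#' @return mM, with attribute `censored` (logical) when a detection limit
#'   is supplied.
#' @export
#' @examples
#' dissolved_gas(0.05, "co2", pH = 7.1)  # feed-gas scale CO2, total DIC
dissolved_gas <- function(partial_pressure, gas, temperature = 30,
                          pH = 7.1, pKa1 = 6.35, speciate = TRUE,
                          detection_limit_mM = NULL,
                          constants = NULL) {
  if (partial_pressure < 0) stop("partial pressure must be >= 0", call. = FALSE)
  tab <- if (is.null(constants)) .HENRY_CONSTANTS else constants
  row <- match(tolower(gas), tolower(tab$gas))
  if (is.na(row)) stop("no Henry constant for gas '", gas, "'", call. = FALSE)
  t_kelvin <- temperature + 273.15
  kh <- tab$kh_298[row] * exp(tab$vant_hoff[row] * (1 / t_kelvin - 1 / 298.15))
  conc_mM <- kh * partial_pressure * 1000
  if (tolower(gas) == "co2" && speciate) {
    conc_mM <- conc_mM * (1 + 10^(pH - pKa1))
  }
  if (!is.null(detection_limit_mM)) {
    attr(conc_mM, "censored") <- conc_mM < detection_limit_mM
    attr(conc_mM, "detection_limit_mM") <- detection_limit_mM
  }
  conc_mM
}

#' Read a steady-state table
#'
#' Reads the CSV dialect used for steady-state summaries: columns
#' `compound`, `phase` (`liquid` or `gas`), `feed_mM`, `residual_mM`.
#'
#' @param path CSV path.
#' @return data.frame with the four columns, validated.
#' @export
read_steady_state <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound", "phase", "feed_mM", "residual_mM")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("steady-state table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(df$phase %in% c("liquid", "gas"))) {
    stop("phase must be 'liquid' or 'gas'", call. = FALSE)
  }
  df
}
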