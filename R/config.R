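#' Load and validate a pipeline configuration
#'
#' Reads a YAML-syntax config and returns validated building blocks:
#' a [reactor_config()], a named list of [species_assay()]s, a
#' [flux_splits()], a [noise_model()], a [biomass_calibration()], and
#' optional measured cell counts. Unknown keys are rejected with a
#' message listing them; a species entry without a genome size loads with
#' the compiled default and a provenance warning.
#'
#' @param path Path to the YAML config.
#' @return A `triflux_config` list with elements `reactor`, `assays`,
#'   `splits`, `noise`, `calibration`, `counts` (or NULL), `path`.
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "tri_culture.yaml",
#'                                package = "triflux"))
#' dilution_rate(cfg$reactor)
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  allowed_top <- c("reactor", "assays", "splits", "noise",
                   "biomass_calibration", "counts_cells_per_ml")
  check_keys(raw, allowed_top, "top level")

  r <- raw$reactor
  allowed_reactor <- c("working_volume_ml", "feed_flow_ml_min",
                       "headspace_gas_flow_ml_min", "temperature_C",
                       "feed_mM", "preset")
  check_keys(r, allowed_reactor, "reactor")
  bad <- character(0)
  for (k in c("working_volume_ml", "feed_flow_ml_min",
              "headspace_gas_flow_ml_min", "temperature_C")) {
    if (!is.null(r[[k]]) && (!is.numeric(r[[k]]) || r[[k]] <= 0)) bad <- c(bad, k)
  }
  if (!is.null(r$feed_mM) && any(unlist(r$feed_mM) < 0)) bad <- c(bad, "feed_mM")
  if (length(bad)) {
    stop("schema violation in reactor section, offending key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  reactor <- reactor_config(
    working_volume = r$working_volume_ml,
    feed_flow = r$feed_flow_ml_min %||% 0.34,
    headspace_gas_flow = r$headspace_gas_flow_ml_min %||% 49,
    temperature = r$temperature_C %||% 30,
    feed = if (is.null(r$feed_mM)) c(cellobiose = 2.2, fumarate = 4.9,
                                     sulfate = 8, NaHCO3 = 5)
           else unlist(r$feed_mM),
    preset = r$preset %||% "reactor"
  )

  assays <- list()
  if (!is.null(raw$assays)) {
    for (a in raw$assays) {
      check_keys(a, c("species", "rrn_copies_per_genome", "genome_size_bp",
                      "primer_pair"), "assay entry")
      assay <- species_assay(a$species,
                             rrn_copies_per_genome = a$rrn_copies_per_genome,
                             genome_size_bp = a$genome_size_bp,
                             primer_pair = a$primer_pair)
      if (assay$genome_size_provenance == "default") {
        warning("assay for ", assay$species,
                ": genome size not supplied, using compiled default (",
                format(assay$genome_size_bp, big.mark = ","), " bp)",
                call. = FALSE)
      }
      assays[[assay$species]] <- assay
    }
  } else {
    d <- default_species_assays()
    assays <- stats::setNames(d, vapply(d, `[[`, "", "species"))
  }

  splits <- if (is.null(raw$splits)) flux_splits() else {
    check_keys(raw$splits, names(formals(flux_splits)), "splits")
    do.call(flux_splits, raw$splits)
  }
  noise <- if (is.null(raw$noise)) noise_model() else {
    check_keys(raw$noise, names(formals(noise_model)), "noise")
    args <- raw$noise
    if (!is.null(args$detection_limits_mM)) {
      args$detection_limits_mM <- unlist(args$detection_limits_mM)
    }
    do.call(noise_model, args)
  }
  calibration <- if (is.null(raw$biomass_calibration)) biomass_calibration() else {
    check_keys(raw$biomass_calibration, names(formals(biomass_calibration)),
               "biomass_calibration")
    do.call(biomass_calibration, raw$biomass_calibration)
  }
  counts <- if (is.null(raw$counts_cells_per_ml)) NULL else unlist(raw$counts_cells_per_ml)

  structure(list(reactor = reactor, assays = assays, splits = splits,
                 noise = noise, calibration = calibration, counts = counts,
                 path = normalizePath(path)),
            class = "triflux_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, allowed, where) {
  if (is.null(x)) return(invisible())
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("schema violation at ", where, ": unknown key(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible()
}

#' Build a chemostat state (and feed) from a steady-state table
#'
#' @param table data.frame as returned by [read_steady_state()].
#' @param od600 Optical density to attach.
#' @param pH Culture pH.
#' @return List with `state` ([chemostat_state()]) and `feed` (named mM
#'   vector from the table's `feed_mM` column).
#' @export
state_from_table <- function(table, od600, pH = 7.1) {
  liquid <- table[table$phase == "liquid", , drop = FALSE]
  residual <- stats::setNames(liquid$residual_mM, liquid$compound)
  gas <- table[table$phase == "gas", , drop = FALSE]
  gas_vec <- stats::setNames(gas$residual_mM, gas$compound)
  list(state = chemostat_state(residual, od600, gas_headspace = gas_vec,
                               pH = pH),
       feed = stats::setNames(liquid$feed_mM, liquid$compound))
}
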