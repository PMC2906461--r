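#' Run manifest
#'
#' Records everything needed to reproduce a run: config and input paths
#' with md5 hashes, the seed, the package version and a timestamp. Every
#' output CSV written by [run_pipeline()] carries a comment line naming
#' the manifest file.
#'
#' @param config_path Path to the YAML config.
#' @param inputs Named character vector of input file paths (may be empty).
#' @param seed Integer seed.
#' @return A `run_manifest` object.
#' @export
run_manifest <- function(config_path, inputs = character(0), seed = 1L) {
  paths <- c(config = config_path, inputs)
  hashes <- vapply(paths, function(p) {
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  }, "")
  structure(list(paths = paths, md5 = hashes, seed = as.integer(seed),
                 package_version = as.character(utils::packageVersion("triflux")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

write_manifest <- function(manifest, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(unclass(manifest), tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

# atomic CSV write with units in headers and a manifest reference comment
write_csv_atomic <- function(df, path, manifest_ref = NULL) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "w")
  if (!is.null(manifest_ref)) writeLines(paste("# manifest:", manifest_ref), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Composes the stages: load config, read the steady-state table, build
#' fluxes, quantify species from a qPCR plate (or use measured counts from
#' the config), and emit the balance report plus a per-day composition
#' table. Deterministic given the seed; writes `report.csv`,
#' `composition.csv` and `manifest.json` under `out_dir` (atomic writes,
#' units in headers, manifest referenced from every CSV) and logs stage
#' progress to stderr.
#'
#' @param config_path YAML config path.
#' @param state_path Steady-state CSV (see [read_steady_state()]).
#' @param od600 Steady-state OD600 (used for community biomass).
#' @param plate_path Optional qPCR plate CSV.
#' @param curves_path Optional standard-curve CSV (`species`, `copies`,
#'   `cq`).
#' @param out_dir Output directory (created if needed); NULL to skip
#'   writing.
#' @param seed Integer seed (recorded; this analysis path is
#'   deterministic).
#' @return List with `report` (a `balance_report`), `composition`
#'   (per-day cells/ml table) and `manifest`.
#' @export
run_pipeline <- function(config_path, state_path, od600 = 0.4,
                         plate_path = NULL, curves_path = NULL,
                         out_dir = NULL, seed = 1L) {
  log_stage <- function(...) message("[triflux] ", ...)

  log_stage("loading config: ", config_path)
  cfg <- load_config(config_path)

  log_stage("reading steady state: ", state_path)
  tab <- tryCatch(read_steady_state(state_path),
                  error = function(e) stop("stage 'state': ",
                                           conditionMessage(e), call. = FALSE))
  st <- state_from_table(tab, od600 = od600)
  reactor <- cfg$reactor
  reactor$feed[names(st$feed)] <- st$feed

  log_stage("allocating fluxes")
  fluxes <- tryCatch(
    allocate_fluxes(st$state, reactor, splits = cfg$splits),
    error = function(e) stop("stage 'fluxes': ", conditionMessage(e),
                             call. = FALSE))

  composition <- NULL
  if (!is.null(plate_path)) {
    log_stage("quantifying species from plate: ", plate_path)
    plate <- utils::read.csv(plate_path, stringsAsFactors = FALSE,
                             comment.char = "#")
    curves <- read_standard_curves(curves_path)
    composition <- quantify_plate(plate, curves, cfg$assays)
    last_day <- max(composition$day)
    late <- composition[composition$day == last_day, , drop = FALSE]
    counts <- stats::setNames(late$cells_per_ml, late$species)
  } else if (!is.null(cfg$counts)) {
    log_stage("using measured counts from config")
    counts <- cfg$counts
    composition <- data.frame(day = NA_real_, species = names(counts),
                              cells_per_ml = unname(counts), sd = NA_real_,
                              n_bio = NA_integer_, flags = "config_counts")
  } else {
    stop("stage 'composition': no plate and no counts in config", call. = FALSE)
  }

  log_stage("building balance report")
  biomass_mg_L <- od_to_biomass(od600, cfg$calibration)
  report <- build_report(fluxes, counts, biomass_mg_L)

  manifest <- run_manifest(config_path,
                           inputs = c(state = state_path,
                                      if (!is.null(plate_path)) c(plate = plate_path),
                                      if (!is.null(curves_path)) c(curves = curves_path)),
                           seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest_path <- file.path(out_dir, "manifest.json")
    write_manifest(manifest, manifest_path)
    rep_df <- as.data.frame(report)
    names(rep_df) <- c("group", "cell_counts_1e8_per_ml", "biomass_mg_dw_per_L",
                       "c_recovered_pct", "e_recovered_pct", "digestible_pct")
    write_csv_atomic(rep_df, file.path(out_dir, "report.csv"), "manifest.json")
    comp <- composition
    names(comp)[names(comp) == "cells_per_ml"] <- "cells_per_ml_culture"
    write_csv_atomic(comp, file.path(out_dir, "composition.csv"), "manifest.json")
    log_stage("wrote report.csv, composition.csv, manifest.json to ", out_dir)
  }
  list(report = report, composition = composition, manifest = manifest)
}

#' Read a standard-curve CSV and fit per-species curves
#'
#' Expected columns: `species`, `copies`, `cq`.
#'
#' @param path CSV path.
#' @return Named list of `standard_curve` objects.
#' @export
read_standard_curves <- function(path) {
  if (is.null(path)) stop("standard-curve CSV required with a plate", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(c("species", "copies", "cq"), names(df))
  if (length(missing)) {
    stop("curve table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$species),
                function(d) fit_standard_curve(d$copies, d$cq))
  out
}

#' Simulate and write observation tables
#'
#' Convenience wrapper for the `simulate` CLI subcommand: runs the
#' deterministic community model, applies the configured noise model, and
#' writes the same CSV dialects the analysis consumes.
#'
#' @param config_path YAML config path.
#' @param duration_days Days simulated.
#' @param seed Integer seed for observation noise.
#' @param out_dir Output directory.
#' @return The `observe()` list, invisibly.
#' @export
simulate_to_csv <- function(config_path, duration_days = 20, seed = 1L,
                            out_dir) {
  cfg <- load_config(config_path)
  sim <- simulate_chemostat(config = cfg$reactor, duration_days = duration_days,
                            seed = seed)
  obs <- observe(sim, noise = cfg$noise, seed = seed,
                 calibration = cfg$calibration)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- run_manifest(config_path, seed = seed)
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  met <- obs$metabolites
  names(met) <- c("day", "compound", "concentration_mM", "censored")
  write_csv_atomic(met, file.path(out_dir, "metabolites.csv"), "manifest.json")
  write_csv_atomic(obs$od, file.path(out_dir, "od.csv"), "manifest.json")
  write_csv_atomic(obs$plate, file.path(out_dir, "plate.csv"), "manifest.json")
  curve_df <- do.call(rbind, lapply(names(obs$curves), function(sp) {
    copies <- 10^(2:8)
    cq <- obs$curves[[sp]]$intercept + obs$curves[[sp]]$slope * log10(copies)
    data.frame(species = sp, copies = copies, cq = cq)
  }))
  write_csv_atomic(curve_df, file.path(out_dir, "curves.csv"), "manifest.json")
  invisible(obs)
}
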