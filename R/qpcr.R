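#' Species-specific qPCR assay definition
#'
#' Carries what absolute quantification needs to turn 16S gene copies into
#' cells: the rRNA operon (rrn) copy number per genome and the genome
#' size. Genome sizes are not part of the assay chemistry and default to
#' compile-time constants from public genome records; override them and
#' the provenance flag clears.
#'
#' @param species One of the registered species names, or any label when
#'   all other fields are given.
#' @param rrn_copies_per_genome Integer >= 1.
#' @param genome_size_bp Genome size in bp (> 1e5).
#' @param primer_pair Optional label of the primer pair (metadata only).
#' @return A `species_assay` object with a `genome_size_provenance` field
#'   (`"default"` or `"user"`).
#' @export
#' @examples
#' species_assay("C. cellulolyticum")
species_assay <- function(species,
                          rrn_copies_per_genome = NULL,
                          genome_size_bp = NULL,
                          primer_pair = NULL) {
  defaults <- default_species_assays()
  key <- match(tolower(species), tolower(vapply(defaults, `[[`, "", "species")))
  provenance <- "user"
  if (!is.na(key)) {
    d <- defaults[[key]]
    if (is.null(rrn_copies_per_genome)) rrn_copies_per_genome <- d$rrn_copies_per_genome
    if (is.null(genome_size_bp)) {
      genome_size_bp <- d$genome_size_bp
      provenance <- "default"
    }
    if (is.null(primer_pair)) primer_pair <- d$primer_pair
    species <- d$species
  }
  if (is.null(rrn_copies_per_genome) || is.null(genome_size_bp)) {
    stop("unknown species '", species,
         "': supply rrn_copies_per_genome and genome_size_bp", call. = FALSE)
  }
  if (rrn_copies_per_genome < 1 || rrn_copies_per_genome != round(rrn_copies_per_genome)) {
    stop("rrn_copies_per_genome must be a positive integer", call. = FALSE)
  }
  if (genome_size_bp <= 1e5) stop("genome_size_bp implausibly small", call. = FALSE)
  structure(list(species = species,
                 rrn_copies_per_genome = as.integer(rrn_copies_per_genome),
                 genome_size_bp = genome_size_bp,
                 genome_size_provenance = provenance,
                 primer_pair = primer_pair),
            class = "species_assay")
}

#' Default assays for the three community members
#'
#' rrn copy numbers: 8 (C. cellulolyticum), 5 (D. vulgaris),
#' 2 (G. sulfurreducens). Genome sizes from public genome records
#' (approximate; override via [species_assay()] for other strains).
#'
#' @return Named list of [species_assay()] definitions.
#' @export
default_species_assays <- function() {
  mk <- function(sp, rrn, gsize, primers) {
    structure(list(species = sp, rrn_copies_per_genome = as.integer(rrn),
                   genome_size_bp = gsize, genome_size_provenance = "default",
                   primer_pair = primers),
              class = "species_assay")
  }
  list(
    c_cellulolyticum = mk("C. cellulolyticum", 8, 4.07e6, "Clos-F/Clos-R"),
    d_vulgaris = mk("D. vulgaris", 5, 3.57e6, "DvH-F/DvH-R"),
    g_sulfurreducens = mk("G. sulfurreducens", 2, 3.81e6, "Geo-F/Geo-R")
  )
}

#' Gene copies in a known mass of DNA
#'
#' copies = ng * 1e-9 * Avogadro / (length_bp * mass_per_bp). The default
#' 660 g/mol/bp is the usual double-stranded average; 650 is accepted in
#' some labs' dialect.
#'
#' @param amount_ng Total DNA in ng (>= 0).
#' @param length_bp Total template length in bp (> 0).
#' @param mass_per_bp g/mol per bp.
#' @return Copy number.
#' @export
#' @examples
#' copies_from_dna_mass(1, 1000)    # ~9.1e8
#' copies_from_dna_mass(1, 4.0e6)   # ~2.3e5 genome copies per ng
copies_from_dna_mass <- function(amount_ng, length_bp, mass_per_bp = 660) {
  if (any(length_bp <= 0)) stop("length_bp must be > 0", call. = FALSE)
  if (any(amount_ng < 0)) stop("amount_ng must be >= 0", call. = FALSE)
  amount_ng * 1e-9 * 6.02214076e23 / (length_bp * mass_per_bp)
}

#' Fit a qPCR standard curve
#'
#' Least-squares regression of Cq on log10(copies) over a serial dilution
#' series. Amplification efficiency is derived as 10^(-1/slope) - 1
#' (slope -3.3219 <-> efficiency 1, i.e. perfect doubling).
#'
#' @param copies Template copies per reaction (>= 3 distinct positive
#'   levels required).
#' @param cq Threshold cycles, same length.
#' @return A `standard_curve` object: `slope`, `intercept`, `efficiency`,
#'   `r_squared`, `range` (min/max copies).
#' @export
#' @examples
#' sc <- fit_standard_curve(10^(3:8), 38 - 3.3219 * (3:8))
#' sc$efficiency # 1
fit_standard_curve <- function(copies, cq) {
  stopifnot(length(copies) == length(cq))
  if (any(copies <= 0)) stop("copies must be positive", call. = FALSE)
  if (length(unique(copies)) < 3L) {
    stop("need >= 3 distinct dilution levels", call. = FALSE)
  }
  lg <- log10(copies)
  if (stats::sd(lg) == 0) stop("zero variance in copies", call. = FALSE)
  fit <- stats::lm(cq ~ lg)
  slope <- unname(stats::coef(fit)[2])
  if (is.na(slope) || slope >= 0) {
    stop("standard curve slope must be negative (Cq decreasing with copies)",
         call. = FALSE)
  }
  eff <- 10^(-1 / slope) - 1
  if (eff < 0.6 || eff > 1.2) {
    warning("amplification efficiency ", round(eff, 2),
            " outside the (0.6, 1.2) band", call. = FALSE)
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((cq - mean(cq))^2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = eff,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 range = range(copies)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> Cq = ", signif(x$intercept, 5), " + ",
      signif(x$slope, 5), " * log10(copies);  E = ",
      round(100 * x$efficiency, 1), "%,  R2 = ", signif(x$r_squared, 4),
      "\n", sep = "")
  invisible(x)
}

#' Interpolate copies from Cq on a standard curve
#'
#' Cq values outside the calibration range are extrapolated with a
#' per-value flag (attribute `extrapolated`), matching common practice.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param cq Threshold cycles.
#' @return Copies per reaction, with logical attribute `extrapolated`.
#' @export
copies_from_cq <- function(curve, cq) {
  copies <- 10^((cq - curve$intercept) / curve$slope)
  extrap <- copies < curve$range[1] | copies > curve$range[2]
  if (any(extrap)) {
    warning(sum(extrap), " value(s) outside the calibration range; ",
            "extrapolated", call. = FALSE)
  }
  attr(copies, "extrapolated") <- extrap
  copies
}

#' Cells per ml of culture from 16S copies per reaction
#'
#' Scales reaction-level copy numbers back to the culture: copies per
#' reaction x (elution volume / template volume per reaction) / culture
#' volume extracted, then divided by the species' 16S copies per genome.
#' Defaults mirror the extraction protocol: 10 ml culture, 100 ul eluate,
#' 0.5 ul template per reaction.
#'
#' @param copies_per_reaction 16S gene copies in one reaction.
#' @param assay A [species_assay()].
#' @param elution_volume_ul Total eluate volume (ul).
#' @param template_volume_ul Eluate volume per reaction (ul).
#' @param sample_volume_ml Culture volume extracted (ml).
#' @return cells/ml.
#' @export
#' @examples
#' # 4e9 16S copies/ml culture at 8 rrn copies -> 5e8 cells/ml
#' cells_per_ml(4e9 / (100 / 0.5) * 10, species_assay("C. cellulolyticum"))
cells_per_ml <- function(copies_per_reaction, assay,
                         elution_volume_ul = 100,
                         template_volume_ul = 0.5,
                         sample_volume_ml = 10) {
  if (!inherits(assay, "species_assay")) {
    stop("assay must be a species_assay", call. = FALSE)
  }
  if (elution_volume_ul <= 0 || template_volume_ul <= 0 || sample_volume_ml <= 0) {
    stop("volumes must be positive", call. = FALSE)
  }
  copies_per_ml_culture <- copies_per_reaction *
    (elution_volume_ul / template_volume_ul) / sample_volume_ml
  copies_per_ml_culture / assay$rrn_copies_per_genome
}

#' Community composition from per-species cell densities
#'
#' @param counts Named numeric vector of cells/ml (>= 0, not all zero).
#' @return A list with `fractions` (summing to 1), `dominant` (name), and
#'   `dominance_ratio` (dominant count over the next largest).
#' @export
#' @examples
#' community_composition(c(Cc = 4.6e8, Dv = 0.29e8, Gs = 0.36e8))
community_composition <- function(counts) {
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("all counts are zero", call. = FALSE)
  fractions <- counts / total
  ord <- order(counts, decreasing = TRUE)
  ratio <- if (length(counts) > 1L && counts[ord[2]] > 0) {
    counts[[ord[1]]] / counts[[ord[2]]]
  } else {
    Inf
  }
  list(fractions = fractions,
       dominant = names(counts)[ord[1]],
       dominance_ratio = ratio)
}

#' Quantify species abundances from a qPCR plate table
#'
#' Takes long-format plate records (columns `sample`, `day`, `species`,
#' `cq`, `bio_rep`, `tech_rep`), averages technical replicates within each
#' biological replicate, interpolates copies on the species' standard
#' curve, converts to cells/ml, and propagates biological replicates as
#' mean and sd.
#'
#' @param plate data.frame in the plate CSV dialect.
#' @param curves Named list of [fit_standard_curve()] results keyed by
#'   species name.
#' @param assays Named list of [species_assay()] objects keyed the same
#'   way; defaults cover the three community members.
#' @param ... Volume overrides passed to [cells_per_ml()].
#' @return data.frame: `day`, `species`, `cells_per_ml`, `sd`, `n_bio`,
#'   `flags` (";"-separated; `extrapolated` when any replicate fell outside
#'   the calibration range, `genome_size_default` when the assay's genome
#'   size is a compiled default).
#' @export
quantify_plate <- function(plate, curves, assays = NULL, ...) {
  required <- c("sample", "day", "species", "cq", "bio_rep", "tech_rep")
  missing <- setdiff(required, names(plate))
  if (length(missing)) {
    stop("plate table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(plate$cq <= 0 | plate$cq > 45)) {
    stop("Cq values must lie in (0, 45]", call. = FALSE)
  }
  if (is.null(assays)) {
    d <- default_species_assays()
    assays <- stats::setNames(d, vapply(d, `[[`, "", "species"))
  }
  out <- list()
  for (sp in unique(plate$species)) {
    if (!sp %in% names(curves)) stop("no standard curve for '", sp, "'", call. = FALSE)
    if (!sp %in% names(assays)) stop("no assay definition for '", sp, "'", call. = FALSE)
    sub <- plate[plate$species == sp, , drop = FALSE]
    for (day in sort(unique(sub$day))) {
      rows <- sub[sub$day == day, , drop = FALSE]
      # mean Cq per biological replicate across its technical replicates
      mean_cq <- tapply(rows$cq, rows$bio_rep, mean)
      copies <- suppressWarnings(copies_from_cq(curves[[sp]], as.numeric(mean_cq)))
      cells <- cells_per_ml(as.numeric(copies), assays[[sp]], ...)
      flags <- character(0)
      if (any(attr(copies, "extrapolated"))) flags <- c(flags, "extrapolated")
      if (assays[[sp]]$genome_size_provenance == "default") {
        flags <- c(flags, "genome_size_default")
      }
      out[[length(out) + 1L]] <- data.frame(
        day = day, species = sp,
        cells_per_ml = mean(cells),
        sd = if (length(cells) > 1L) stats::sd(cells) else NA_real_,
        n_bio = length(cells),
        flags = paste(flags, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
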