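test_that("DNA mass to copies matches the unit-analysis oracle", {
  expect_equal(copies_from_dna_mass(0, 1000), 0)
  expect_equal(copies_from_dna_mass(1, 1000), copies_oracle(1, 1000))
  expect_equal(copies_from_dna_mass(1, 1000) / 1e8, 9.12, tolerance = 1e-3)
  expect_equal(copies_from_dna_mass(1, 4.0e6) / 1e5, 2.28, tolerance = 1e-2)
  # linear in amount, inverse in length
  expect_equal(copies_from_dna_mass(5, 1000), 5 * copies_from_dna_mass(1, 1000))
  expect_equal(copies_from_dna_mass(1, 2000), copies_from_dna_mass(1, 1000) / 2)
  # 650 vs 660 g/mol/bp dialects
  expect_equal(copies_from_dna_mass(1, 1000, mass_per_bp = 650),
               copies_oracle(1, 1000, 650))
  expect_error(copies_from_dna_mass(1, 0), "> 0")
})

test_that("standard curves recover known parameters", {
  # perfect doubling
  sc <- fit_standard_curve(10^(3:8), 38 - 3.321928 * (3:8))
  expect_equal(sc$efficiency, 1, tolerance = 1e-6)
  expect_equal(sc$r_squared, 1)
  # exact recovery of arbitrary noiseless parameters
  for (params in list(c(-3.1, 36), c(-3.6, 40), c(-3.3219, 35))) {
    copies <- 10^seq(2, 7, by = 0.5)
    fit <- fit_standard_curve(copies, params[2] + params[1] * log10(copies))
    expect_equal(fit$slope, params[1], tolerance = 1e-10)
    expect_equal(fit$intercept, params[2], tolerance = 1e-10)
  }
  # noisy recovery within +-0.1 at sigma 0.1
  set.seed(101)
  copies <- rep(10^(2:8), each = 3)
  cq <- 37 - 3.5 * log10(copies) + rnorm(length(copies), 0, 0.1)
  fit <- fit_standard_curve(copies, cq)
  expect_equal(fit$slope, -3.5, tolerance = 0.1 / 3.5)
  # degenerate inputs
  expect_error(fit_standard_curve(c(10, 100), c(30, 27)), "3 distinct")
  expect_error(fit_standard_curve(rep(100, 4), c(30, 30, 30, 30)), "distinct")
  expect_error(fit_standard_curve(10^(1:4), rep(30, 4)), "negative")
  expect_warning(fit_standard_curve(10^(3:8), 38 - 2 * (3:8)), "efficiency")
})

test_that("Cq interpolation flags extrapolation beyond the calibration range", {
  sc <- fit_standard_curve(10^(3:7), 38 - 3.3219 * (3:7))
  inside <- copies_from_cq(sc, 38 - 3.3219 * 5)
  expect_equal(as.numeric(inside), 1e5, tolerance = 1e-6)
  expect_false(any(attr(inside, "extrapolated")))
  expect_warning(out <- copies_from_cq(sc, 10), "extrapolated")
  expect_true(attr(out, "extrapolated"))
})

test_that("cells_per_ml applies extraction scaling and rrn correction", {
  cc <- species_assay("C. cellulolyticum")
  # 4e9 16S copies/ml culture: reaction sees /200 (100 ul eluate, 0.5 ul
  # per rxn) x10 (10 ml culture) less material
  copies_rxn <- 4e9 * 10 / (100 / 0.5)
  expect_equal(cells_per_ml(copies_rxn, cc), 5.0e8)
  gs <- species_assay("G. sulfurreducens")
  expect_equal(cells_per_ml(5.0e7 * 10 / 200, gs), 2.5e7)
  expect_error(cells_per_ml(1, cc, sample_volume_ml = 0), "positive")
  expect_error(species_assay("E. coli"), "unknown species")
  # user-specified species bypasses the registry
  ec <- species_assay("E. coli", rrn_copies_per_genome = 7,
                      genome_size_bp = 4.6e6)
  expect_equal(ec$genome_size_provenance, "user")
})

test_that("default assays carry the 8/5/2 rrn copy numbers", {
  d <- default_species_assays()
  expect_equal(vapply(d, `[[`, 0L, "rrn_copies_per_genome"),
               c(c_cellulolyticum = 8L, d_vulgaris = 5L, g_sulfurreducens = 2L))
  expect_true(all(vapply(d, `[[`, 0, "genome_size_bp") > 1e6))
})

test_that("cells -> plate -> cells round trip is accurate and unbiased", {
  sc <- fit_standard_curve(10^(2:8), 38 - 3.3219 * (2:8))
  assay <- species_assay("D. vulgaris")
  truth <- 3e7
  to_cq <- function(cells, sd_cq, n) {
    copies_rxn <- cells * assay$rrn_copies_per_genome * 10 / 200
    38 - 3.3219 * log10(copies_rxn) + rnorm(n, 0, sd_cq)
  }
  set.seed(5)
  # single noisy read within 5% at sigma 0.1 (averaged over 9 replicates)
  cq <- to_cq(truth, 0.1, 9)
  est <- mean(cells_per_ml(as.numeric(suppressWarnings(copies_from_cq(sc, cq))),
                           assay))
  expect_equal(est, truth, tolerance = 0.05)
  # mean relative error shrinks toward zero as replication grows
  err_for <- function(n) {
    mean(replicate(40, {
      est <- mean(cells_per_ml(
        as.numeric(suppressWarnings(copies_from_cq(sc, to_cq(truth, 0.2, n)))),
        assay))
      (est - truth) / truth
    }))
  }
  expect_lt(abs(err_for(30)), 0.02)
})

test_that("community composition normalizes and ranks correctly", {
  comp <- community_composition(c(Cc = 4.6e8, Dv = 0.29e8, Gs = 0.36e8))
  expect_equal(unname(comp$fractions), c(0.876, 0.055, 0.069), tolerance = 1e-2)
  expect_equal(sum(comp$fractions), 1)
  expect_equal(comp$dominant, "Cc")
  expect_gt(comp$dominance_ratio, 10)
  expect_equal(unname(community_composition(c(a = 5))$fractions), 1)
  expect_equal(unname(community_composition(c(a = 2, b = 2, c = 2))$fractions),
               rep(1 / 3, 3))
  expect_error(community_composition(c(a = 0, b = 0)), "zero")
  # property: fractions always sum to 1
  set.seed(3)
  for (i in 1:20) {
    x <- runif(sample(2:5, 1), 0, 1e9)
    names(x) <- paste0("s", seq_along(x))
    expect_equal(sum(community_composition(x)$fractions), 1)
  }
})

test_that("quantify_plate averages replicates and propagates flags", {
  sc <- fit_standard_curve(10^(2:8), 38 - 3.3219 * (2:8))
  assay <- species_assay("D. vulgaris")
  cells_true <- 2.9e7
  copies_rxn <- cells_true * 5 * 10 / 200
  cq0 <- 38 - 3.3219 * log10(copies_rxn)
  plate <- expand.grid(bio_rep = 1:3, tech_rep = 1:3)
  plate$sample <- "d10_b"
  plate$day <- 10
  plate$species <- "D. vulgaris"
  plate$cq <- cq0
  out <- quantify_plate(plate, curves = list("D. vulgaris" = sc),
                        assays = list("D. vulgaris" = assay))
  expect_equal(nrow(out), 1)
  expect_equal(out$cells_per_ml, cells_true, tolerance = 1e-6)
  expect_equal(out$n_bio, 3)
  expect_match(out$flags, "genome_size_default")
  expect_error(quantify_plate(plate[, -4], list()), "missing column")
  bad <- plate
  bad$cq[1] <- 50
  expect_error(quantify_plate(bad, list("D. vulgaris" = sc)), "45")
})
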