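test_that("flux allocation reproduces the measured per-mole yields", {
  ft <- paper_flux_table()
  net <- community_fluxes(ft)
  yield <- function(cmpd) net$mol_per_mol_cellobiose[net$compound == cmpd]
  expect_equal(round(yield("acetate"), 1), 2.7)
  expect_equal(round(-yield("fumarate"), 2), 2.23)
  expect_equal(round(-yield("sulfate"), 1), 2.8) # 6.1/2.2
  expect_equal(round(yield("co2"), 1), 3.3)      # fermenter 2.7 + respirer 0.6
  expect_equal(attr(ft, "basis_mM"), 2.2)
  # acceptor respiration stoichiometry: 0.3 acetate -> 0.6 CO2
  gs <- ft[ft$species == "G. sulfurreducens", ]
  expect_equal(gs$mol_per_mol_cellobiose[gs$compound == "co2"], 0.6)
  expect_equal(gs$mol_per_mol_cellobiose[gs$compound == "acetate"], -0.45)
  # only the fermenter touches cellobiose
  expect_equal(unique(ft$species[ft$compound == "cellobiose"]),
               "C. cellulolyticum")
})

test_that("community totals decompose exactly over species", {
  ft <- paper_flux_table()
  net <- community_fluxes(ft, drop_zero = FALSE)
  for (cmpd in unique(ft$compound)) {
    expect_equal(net$mol_per_mol_cellobiose[net$compound == cmpd],
                 sum(ft$mol_per_mol_cellobiose[ft$compound == cmpd]),
                 info = cmpd)
  }
  # the cross-fed donor pool cancels at community level
  net_drop <- community_fluxes(ft)
  expect_false(any(c("hydrogen", "ethanol") %in% net_drop$compound))
})

test_that("allocation validates inputs and warns on donor shortfall", {
  cfg <- reactor_config()
  no_consumption <- chemostat_state(residual = c(cellobiose = 2.2), od600 = 0)
  expect_error(allocate_fluxes(no_consumption, cfg), "no cellobiose")
  # sulfate fully consumed demands more electrons than cellobiose supplies
  greedy <- chemostat_state(
    residual = c(cellobiose = 0, acetate = 5.93, fumarate = 0,
                 succinate = 3.586, malate = 0.044, sulfate = 0),
    od600 = 0.4)
  expect_warning(allocate_fluxes(greedy, cfg), "donor capacity")
})

test_that("carbon recovery reproduces the community balance", {
  ft <- paper_flux_table()
  expect_equal(round(carbon_recovery(ft, biomass_mg_L = 236)), 93)
  # excluding biomass loses the cell-mass carbon
  expect_lt(carbon_recovery(ft), carbon_recovery(ft, biomass_mg_L = 236))
  # linearity: halving all products halves recovery
  net <- community_fluxes(ft)
  halved <- net
  pos <- halved$mol_per_mol_cellobiose > 0
  halved$mol_per_mol_cellobiose[pos] <- halved$mol_per_mol_cellobiose[pos] / 2
  expect_equal(carbon_recovery(halved), carbon_recovery(net) / 2)
  expect_error(carbon_recovery(net[0, ]), "empty")
  no_c <- data.frame(compound = c("sulfate", "sulfide"),
                     mol_per_mol_cellobiose = c(-1, 1))
  expect_error(carbon_recovery(no_c), "zero carbon")
})

test_that("electron recovery reproduces the community balance", {
  ft <- paper_flux_table()
  er <- electron_recovery(ft, biomass_mg_L = 236)
  expect_equal(er, 112, tolerance = 1 / 112) # printed intermediates round
  # sulfide carries the 8 e-/mol of the sulfate couple: removing it drops
  # the recovery by exactly 8 x 2.77 / inputs
  net <- community_fluxes(ft)
  no_sulfide <- net[net$compound != "sulfide", ]
  drop <- er - electron_recovery(no_sulfide, biomass_mg_L = 236,
                                 basis_mM = 2.2)
  expect_equal(drop, 100 * 8 * (6.1 / 2.2) / (48 + 12 * 4.9 / 2.2),
               tolerance = 1e-9)
  expect_error(electron_recovery(net[net$compound == "sulfide", , drop = FALSE]),
               "zero electron")
})

test_that("balanced synthetic flux tables recover exactly 100/100", {
  # community fluxes assembled from the generator's balanced reactions:
  # conservation must hold for any non-negative rate mix
  set.seed(23)
  nus <- list(fermenter_stoichiometry(), srb_stoichiometry(),
              geobacter_stoichiometry())
  for (i in 1:10) {
    r <- c(runif(1, 0.5, 2), runif(1, 0.001, 0.02), runif(1, 0.005, 0.05))
    net <- c(biomass_total = 0)
    for (k in 1:3) {
      for (cmpd in names(nus[[k]])) {
        net[cmpd] <- (if (cmpd %in% names(net)) net[[cmpd]] else 0) +
          r[k] * nus[[k]][[cmpd]]
      }
    }
    net <- net[setdiff(names(net), "biomass_total")]
    df <- data.frame(compound = names(net), mol_per_mol_cellobiose = unname(net))
    biomass_mM <- sum(r) # 1 mol biomass per unit rate
    basis <- -net[["cellobiose"]]
    expect_equal(carbon_recovery(df, biomass_mg_L = biomass_mM * 104,
                                 basis_mM = basis / basis),
                 100, tolerance = 1e-6)
    expect_equal(electron_recovery(df, biomass_mg_L = biomass_mM * 104,
                                   basis_mM = basis / basis),
                 100, tolerance = 1e-6)
  }
})

test_that("adding a carbon-bearing product strictly increases carbon recovery", {
  net <- community_fluxes(paper_flux_table())
  before <- carbon_recovery(net)
  set.seed(9)
  for (i in 1:5) {
    extra <- net
    extra$mol_per_mol_cellobiose[extra$compound == "acetate"] <-
      extra$mol_per_mol_cellobiose[extra$compound == "acetate"] + runif(1, 0.01, 1)
    expect_gt(carbon_recovery(extra), before)
  }
})

test_that("digestible-energy fraction matches the independent hand calculation", {
  ft <- paper_flux_table()
  # hand calculation from the printed mM values: digestible electron
  # equivalents (acetate 5.93x8, succinate 3.586x14, malate 0.044x12) over
  # inputs (cellobiose 2.2x48 + fumarate 4.9x12)
  hand <- 100 * (5.93 * 8 + 3.586 * 14 + 0.044 * 12) / (2.2 * 48 + 4.9 * 12)
  expect_equal(digestible_energy_fraction(ft), hand, tolerance = 1e-9)
  expect_equal(round(digestible_energy_fraction(ft)), 60)
  # empty digestible flux -> 0
  net <- community_fluxes(ft)
  none <- net[!net$compound %in% c("acetate", "succinate", "malate"), ]
  expect_equal(digestible_energy_fraction(none), 0)
  # pass-through: inputs re-emitted unchanged -> 100
  passthru <- data.frame(compound = "acetate",
                         mol_per_mol_cellobiose = c(-1, 1))
  expect_equal(digestible_energy_fraction(passthru), 100)
  # relabeling invariance: swapping equal mol x gamma products changes nothing
  a <- data.frame(compound = c("cellobiose", "acetate"),
                  mol_per_mol_cellobiose = c(-1, 3))
  b <- data.frame(compound = c("cellobiose", "succinate"),
                  mol_per_mol_cellobiose = c(-1, 3 * 8 / 14))
  expect_equal(digestible_energy_fraction(a), digestible_energy_fraction(b))
  # malate excludable by config
  expect_lt(digestible_energy_fraction(ft, digestible = c("acetate", "succinate",
                                                          "ethanol", "hydrogen")),
            digestible_energy_fraction(ft))
  expect_error(digestible_energy_fraction(ft, digestible = character(0)), "empty")
})

test_that("biomass partition is proportional and sums exactly", {
  shares <- partition_biomass(236, paper_counts())
  expect_equal(unname(shares), c(206.9, 13.0, 16.2), tolerance = 1e-3)
  expect_equal(sum(shares), 236)
  expect_equal(unname(partition_biomass(100, c(only = 5e8))), 100)
  expect_equal(unname(partition_biomass(90, c(a = 2, b = 2, c = 2))),
               rep(30, 3))
  # weights shift the split
  w <- partition_biomass(100, c(a = 1, b = 1), c(a = 3, b = 1))
  expect_equal(unname(w), c(75, 25))
  expect_error(partition_biomass(100, c(a = 0, b = 0)), "zero")
  # property: always sums to input
  set.seed(17)
  for (i in 1:20) {
    x <- runif(3, 0, 1e9)
    names(x) <- c("a", "b", "c")
    total <- runif(1, 1, 500)
    expect_equal(sum(partition_biomass(total, x)), total)
  }
})

test_that("build_report emits the five-column community and species rows", {
  ft <- paper_flux_table()
  rep <- build_report(ft, paper_counts(), 236)
  expect_s3_class(rep, "balance_report")
  expect_equal(rep$group, c("community", "C. cellulolyticum", "D. vulgaris",
                            "G. sulfurreducens"))
  comm <- rep[rep$group == "community", ]
  expect_equal(comm$cell_counts_1e8, 5.25)
  expect_equal(comm$biomass_mg_L, 236)
  expect_equal(round(comm$c_recovered_pct), 93)
  expect_equal(comm$e_recovered_pct, 112, tolerance = 1 / 112)
  # species biomass decomposes to the community total
  expect_equal(sum(rep$biomass_mg_L[-1]), comm$biomass_mg_L)
  # the sulfate reducer's electron recovery above 100% is expected, not an error
  expect_true(rep$e_recovered_pct[rep$group == "D. vulgaris"] > 100)
  # the unresolved donor pool is flagged
  expect_match(paste(attr(rep, "flags"), collapse = " "), "unresolved_donor_pool")
  # serialization round-trips through CSV
  path <- tempfile(fileext = ".csv")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$c_recovered_pct, rep$c_recovered_pct, tolerance = 1e-9)
  expect_equal(attr(back, "flags"), attr(rep, "flags"))
})
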