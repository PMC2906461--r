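test_that("stoichiometry constructors are balanced for any parameters", {
  set.seed(31)
  for (i in 1:15) {
    reactions <- list(
      fermenter_stoichiometry(runif(1, 0.9, 1.3), runif(1, 0, 0.2)),
      srb_stoichiometry(runif(1, 10, 40), runif(1, 0, 0.2)),
      geobacter_stoichiometry(runif(1, 15, 50), runif(1, 0, 0.05))
    )
    for (nu in reactions) {
      imb <- triflux:::.reaction_imbalance(nu)
      expect_lt(max(abs(imb)), 1e-9)
    }
  }
  expect_error(fermenter_stoichiometry(0.3), "no room")
})

test_that("the simulator refuses an unbalanced reaction set", {
  broken <- sim_species("broken", 0.1, ks = c(cellobiose = 0.1),
                        stoich = c(cellobiose = -1, acetate = 1))
  expect_error(simulate_chemostat(species = list(broken), duration_days = 1),
               "unbalanced")
})

test_that("washout follows chemostat theory around the mu_max = D threshold", {
  cfg <- reactor_config()
  D <- dilution_rate(cfg)
  mk <- function(mu) list(sim_species("fermenter", mu, c(cellobiose = 0.1),
                                      fermenter_stoichiometry()))
  run <- function(mu) {
    simulate_chemostat(cfg, mk(mu), duration_days = 12,
                       inoculum_mg_L = c(fermenter = 16),
                       solver = "rk45", rtol = 1e-8)
  }
  # mu_max below D: biomass decays, residual returns to the feed
  washed <- run(0.65 * D)
  x <- washed$biomass[, 1]
  expect_true(all(diff(x) < 0))
  expect_lt(x[length(x)], 0.1 * x[1])
  expect_gt(washed$conc[nrow(washed$conc), "cellobiose"], 2.0)
  # at the bifurcation point the Monod factor keeps mu below D: still decays
  at_thresh <- run(D)
  expect_true(all(diff(at_thresh$biomass[, 1]) < 0))
  # comfortably above D the species persists and draws the substrate down
  alive <- run(1.5 * D)
  expect_gt(alive$biomass[nrow(alive$biomass), 1], 5 * 16)
  expect_lt(alive$conc[nrow(alive$conc), "cellobiose"], 0.5)
})

test_that("with no biomass the residuals relax to the feed at rate D", {
  cfg <- reactor_config()
  D <- dilution_rate(cfg)
  sp <- list(sim_species("fermenter", 0.15, c(cellobiose = 0.1),
                         fermenter_stoichiometry()))
  sim <- simulate_chemostat(cfg, sp, duration_days = 6,
                            inoculum_mg_L = c(fermenter = 0),
                            initial_conc = c(cellobiose = 0),
                            solver = "rk45", rtol = 1e-10, atol = 1e-12)
  s_in <- cfg$feed[["cellobiose"]]
  expected <- s_in + (0 - s_in) * exp(-D * sim$times_days * 24)
  expect_equal(unname(sim$conc[, "cellobiose"]), expected, tolerance = 1e-7)
})

test_that("the default preset reaches the expected steady state and conserves mass", {
  sim <- get_default_sim()
  nT <- nrow(sim$conc)
  final <- sim$conc[nT, ]
  # fumarate removed completely; sulfate left over; cellobiose nearly gone
  expect_lt(final[["fumarate"]], 0.1)
  expect_gt(final[["sulfate"]], 0.5)
  expect_lt(final[["cellobiose"]], 0.2)
  # dissolved hydrogen in the sub-micromolar range
  expect_lt(final[["hydrogen"]], 1e-3)
  # OD near the observed 0.4, fermenter-dominated biomass
  expect_equal(sim$od600[nT], 0.4, tolerance = 0.15)
  expect_gt(sim$biomass[nT, "C. cellulolyticum"], 10 * sim$biomass[nT, "D. vulgaris"])
  # carbon and electron closure along the trajectory, to solver tolerance
  expect_equal(sim$conservation$carbon_closure, 1, tolerance = 1e-5)
  expect_equal(sim$conservation$electron_closure, 1, tolerance = 1e-5)
  # steady: last two output points agree
  expect_equal(sim$conc[nT, ], sim$conc[nT - 1, ], tolerance = 1e-3)
})

test_that("observation with zero noise reproduces the simulation exactly", {
  sim <- get_default_sim()
  quiet <- noise_model(0, 0, 0, 0, 0, detection_limits_mM = numeric(0))
  obs <- observe(sim, quiet, seed = 99)
  for (d in c(5, 20)) {
    idx <- which(sim$times_days == d)
    met <- obs$metabolites[obs$metabolites$day == d, ]
    expect_equal(stats::setNames(met$concentration_mM, met$compound),
                 pmax(sim$conc[idx, ], 0))
    expect_false(any(met$censored))
  }
  # plate -> quantification recovers the true cell densities
  out <- quantify_plate(obs$plate[obs$plate$day == 20, ], obs$curves)
  truth <- obs$truth[obs$truth$day == 20, ]
  for (k in seq_len(nrow(truth))) {
    est <- out$cells_per_ml[out$species == truth$species[k]]
    expect_equal(est, truth$cells_per_ml[k], tolerance = 1e-6)
  }
})

test_that("detection limits censor the hydrogen observation", {
  sim <- get_default_sim()
  obs <- observe(sim, noise_model(), seed = 4)
  h2 <- obs$metabolites[obs$metabolites$compound == "hydrogen" &
                          obs$metabolites$day == 20, ]
  expect_true(h2$censored)
  expect_equal(h2$concentration_mM, 3e-4) # reported as "< 0.3 uM"
})

test_that("observation is deterministic for a fixed seed and preserves the RNG", {
  sim <- get_default_sim()
  a <- observe(sim, noise_model(), seed = 7, days = c(18, 19, 20))
  b <- observe(sim, noise_model(), seed = 7, days = c(18, 19, 20))
  expect_identical(a$metabolites, b$metabolites)
  expect_identical(a$plate, b$plate)
  c_ <- observe(sim, noise_model(), seed = 8, days = c(18, 19, 20))
  expect_false(identical(a$plate$cq, c_$plate$cq))
  set.seed(1)
  x1 <- runif(1)
  set.seed(1)
  invisible(observe(sim, noise_model(), seed = 7, days = 20))
  expect_identical(x1, runif(1))
})

test_that("sporulation upsets let cellobiose climb toward the feed", {
  base <- tri_culture_scenario(duration_days = 7)
  upset <- make_upset_scenario(base, "sporulation", window_days = c(3, 5))
  sim <- run_scenario(upset)
  cb <- sim$conc[, "cellobiose"]
  t <- sim$times_days
  during <- cb[t >= 4.5 & t < 5]
  before <- cb[t >= 2.5 & t < 3]
  expect_gt(max(during), 10 * max(before))
  expect_true(all(cb <= 2.2 + 1e-6))
  # after the window the fermenter recovers
  expect_lt(cb[length(cb)], max(during))
  expect_error(make_upset_scenario(base, "volcano"), "arg")
})

test_that("high-fumarate upsets engage succinate inhibition of the fermenter", {
  base <- tri_culture_scenario()
  upset <- make_upset_scenario(base, "high_fumarate", fumarate_feed_mM = 12)
  expect_equal(upset$config$feed[["fumarate"]], 12)
  # inhibition term evaluated at succinate above threshold: growth < D even
  # with saturating cellobiose
  ferm <- default_sim_species()[["C. cellulolyticum"]]
  mu_at <- function(succ) {
    ferm$mu_max * (2.2 / (ferm$ks[["cellobiose"]] + 2.2)) /
      (1 + (succ / ferm$inhibition$threshold_mM)^ferm$inhibition$hill)
  }
  D <- dilution_rate(reactor_config())
  expect_gt(mu_at(5), D)
  expect_lt(mu_at(15), D)
  # events: an empty list is the base case
  s0 <- simulate_chemostat(duration_days = 1, events = NULL)
  s1 <- simulate_chemostat(duration_days = 1, events = list())
  expect_identical(s0$conc, s1$conc)
})
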