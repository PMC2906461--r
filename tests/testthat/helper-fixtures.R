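# Shared fixtures. The measured steady state (mM): cellobiose exhausted,
# 5.93 acetate, fumarate fully removed with 1.63 succinate and 0.02 malate
# per mole cellobiose, 6.1 of 8 mM sulfate reduced.
paper_state <- function() {
  chemostat_state(
    residual = c(cellobiose = 0, acetate = 5.93, fumarate = 0,
                 succinate = 1.63 * 2.2, malate = 0.02 * 2.2, sulfate = 1.9),
    od600 = 0.4
  )
}

paper_counts <- function() {
  c("C. cellulolyticum" = 4.6e8, "D. vulgaris" = 0.29e8,
    "G. sulfurreducens" = 0.36e8)
}

paper_flux_table <- function() {
  allocate_fluxes(paper_state(), reactor_config())
}

# The default community simulation is expensive (~15 s); run it at most
# once per test session and share across files.
get_default_sim <- local({
  cache <- NULL
  function(duration_days = 20) {
    if (is.null(cache)) {
      cache <<- simulate_chemostat(duration_days = duration_days)
    }
    cache
  }
})

# effective per-mole-cellobiose yields of a sim at its final time point
sim_yields <- function(sim) {
  nT <- nrow(sim$conc)
  feed <- sim$config$feed
  cb <- feed[["cellobiose"]] - sim$conc[nT, "cellobiose"]
  c(acetate = unname(sim$conc[nT, "acetate"] / cb),
    succinate = unname(sim$conc[nT, "succinate"] / cb),
    sulfate_reduced = unname((feed[["sulfate"]] - sim$conc[nT, "sulfate"]) / cb))
}
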