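Package: triflux
Title: Carbon and Electron Flux Accounting for a Model Anaerobic Tri-Culture Chemostat
Version: 0.1.0
Authors@R:
    person("Lab", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous cultures of a three-species
    anaerobic consortium (a cellulolytic fermenter, a sulfate reducer and a
    fumarate-respiring metal reducer): degree-of-reduction electron
    bookkeeping for elemental formulas, chemostat steady-state flux
    accounting, absolute quantification of community members from 16S qPCR
    with rRNA operon copy-number correction, a trophic carbon/electron
    mass-balance model producing community and per-species recovery
    reports, and a mass- and electron-conserving chemostat simulator with
    realistic measurement noise so the whole pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
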