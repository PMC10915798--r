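Package: ionbridge
Title: Buffer-Ion Adsorption, Screening and Bridging Analysis for Protein Simulations
Version: 0.1.0
Authors@R:
    person("Ion", "Bridge", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying how buffer ions (phosphate, citrate,
    histidine and simple salts) interact with protein surfaces in molecular
    simulation trajectories. Implements Henderson-Hasselbalch speciation of
    polyprotic buffers, surface radial distribution functions, per-residue
    contact counting and the Buffer Adsorption Index (a relative adsorption
    free energy in units of kT), effective-charge/charge-compensation profiles
    with screening-length fits, contact and ionic-bridge survival kinetics,
    and minimum-distance free-energy profiles for protein dimers. Ships a
    synthetic trajectory generator (Metropolis equilibrium sampler, telegraph
    contact kinetics, two-protein bridging systems) with known ground truth so
    every analysis stage is testable without molecular dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
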