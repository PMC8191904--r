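Package: slurrygas
Title: Mechanistic Simulation of Methane Emission from Stored Animal Slurry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates methane, carbon dioxide and hydrogen sulfide emission
    from stored animal slurry (pits, channels, outside tanks) with a
    semi-batch reactor model on a chemical oxygen demand (COD) basis.
    Multiple methanogen populations with cardinal-temperature (CTM1)
    kinetics compete for volatile fatty acids, optionally against a
    sulfate-reducing population (double-Monod); first-order hydrolysis
    feeds the substrate pool and decayed biomass is recycled. Slurry
    management is explicit: constant filling, threshold-triggered
    instantaneous emptying with a residual fraction, and biofilm-mediated
    microbial enrichment of the residue (log-odds retention model).
    Includes pH, ammonia, ammonium and hydrogen sulfide inhibition,
    temperature-dependent chemical speciation, COD/sulfur/nitrogen balance
    audits, scripted in-silico experiments (residual-fraction sweeps,
    temperature regimes, acidification, one-at-a-time sensitivity), a YAML
    scenario format and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
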