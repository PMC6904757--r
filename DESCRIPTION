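Package: megaflux
Title: Constraint-Based Analysis of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Flux balance analysis (FBA), suboptimal flux variability
    analysis (FVA), minimum-total-flux distributions, flux-sum metabolite
    turnover, gene-protein-reaction (GPR) Boolean logic and knockouts,
    medium and carbon-source phenotype screening, batch-culture growth
    kinetics (specific growth rate and substrate uptake estimation),
    two-stage production simulations and dose-response uptake scans for
    genome-scale metabolic models, with readers and writers for SBML
    Level 3 + FBC v2 and a JSON dialect, deterministic synthetic network
    generators with planted optima, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    xml2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
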