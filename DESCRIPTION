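Package: condnuc
Title: Nucleation Kinetics of Biomolecular Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative framework for the nucleation kinetics of
    biomolecular condensates. Implements binary Flory-Huggins
    thermodynamics with convex-hull binodal construction, classical
    nucleation theory rates for both void nucleation inside condensates
    and condensate nucleation from dilute solution, a moving-boundary
    finite-difference model of a cooling condensate, Poisson void-count
    statistics with interfacial-tension fitting, reduction of FRAP and
    fusion measurements to transport coefficients, and nucleation-propensity
    predictions across condensate and solid systems. Ships synthetic-data
    generators so the full pipeline is testable without experimental inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
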