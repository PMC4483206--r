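Package: translung
Title: Nanoparticle Translocation Across the Lung Epithelial Barrier and
    Whole-Body Biokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the combined in vitro / in silico assessment of the
    biokinetics of inhaled or instilled nanoparticles. A mechanistic simulator
    of the air-liquid-interface transwell exposure experiment (three-compartment
    disposition, daily basolateral sampling, recovery losses, detection limits)
    generates translocation-fraction data; a whole-body physiologically based
    pharmacokinetic (PBPK) model with capillary-wall-type-grouped organ uptake,
    mucociliary, biliary and urinary clearance then simulates the distribution
    of translocated particles to secondary organs. Inference utilities fit the
    lung-to-blood translocation rate to measured fractions, compute the
    biliary-excretion adjustment factor that converts secondary-organ-based
    translocation measurements into total translocation, derive bound scenarios
    from biodistribution records, and propagate log-normal parameter
    uncertainty by Monte Carlo simulation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
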