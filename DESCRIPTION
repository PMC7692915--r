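Package: csaflux
Title: Cotton-Strip Assay Decomposition, Activation Energies, Carbon
    Efflux and Microbial Diversity in Wastewater-Impacted Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing standardized cotton-strip assays of
    organic-matter decomposition in streams receiving treated wastewater.
    Computes microbial respiration from dissolved-oxygen budgets, tensile
    strength and mass decay coefficients on day and temperature-day bases,
    fits linearized Arrhenius mixed models to estimate activation energies
    by sampling location, converts respiration to areal carbon dioxide
    evasion with bootstrap uncertainty and national upscaling, and analyses
    OTU count tables (alpha diversity with rarefaction and extrapolation,
    turnover and nestedness partitioning of beta diversity, ordination,
    strata-restricted PERMANOVA and dispersion tests). Includes seeded
    generators that simulate the paired upstream and downstream survey,
    flume and laboratory-transplant designs, so the whole pipeline can be
    exercised and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    emmeans,
    vegan,
    jsonlite,
    rlang,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
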