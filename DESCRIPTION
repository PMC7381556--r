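Package: grazekit
Title: High-Throughput Feeding-Rate Estimation from 96-Well Plate Fluorometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying individual clearance (feeding) rates of small
    aquatic grazers from in vivo chlorophyll-a fluorescence read on 96-well
    microplates. Parses plate-reader grid and long-format exports, joins plate
    layouts and animal metadata, summarizes plate-specific consumer-free
    controls, and estimates per-individual clearance rates from exponential
    resource depletion, f = (V/t) ln(F0/Ft), with quality-control exclusions
    (negative rates, deaths, males), unit conversion, and percentile bootstrap
    confidence intervals. Includes linear standard-curve calibration
    (fluorescence vs biomass), blocked Type III ANOVA with Shapiro-Wilk
    diagnostics and Tukey-Kramer simultaneous confidence intervals for genotype
    comparisons, an extension for assays with fluorescent background stressors
    (pathogen or contaminant exposure rates and cumulative doses), and a
    seeded synthetic assay simulator for parameter-recovery and error-rate
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
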