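Package: d2oturnover
Title: Heavy-Water Labelling Analysis of Skeletal Muscle Protein Turnover
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for deuterium oxide (D2O) metabolic labelling
    experiments in skeletal muscle under non-steady-state conditions such as
    cancer cachexia. Converts GC-MS alanine isotopomer distributions and
    plasma body-water enrichment into fraction-new protein via mass
    isotopomer distribution analysis (MIDA), and estimates first-order
    synthesis and degradation rate constants from the pool model
    dP/dt = ksyn - kdeg * P using the pool-size ratio to relax the
    steady-state assumption. Includes the supporting assay computations of a
    2x2 (genotype x tumour) cachexia study (delta-delta-Ct expression,
    antimycin-A-corrected respirometry, fibre cross-sectional-area binning,
    tumour-free mass normalisation), a self-contained two-way ANOVA with
    Tukey-Kramer post hoc built on a numerically integrated studentized
    range distribution, and a synthetic-cohort generator with known ground
    truth so every stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'isotopomers.R'
    'enrichment.R'
    'kinetics.R'
    'cohort.R'
    'assays.R'
    'anova.R'
    'tukey.R'
    'pipeline.R'
    'pool.R'
    'protocol.R'
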