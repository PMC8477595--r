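Package: rdnaclock
Title: Ribosomal DNA Methylation Clocks for Crustacean Age Estimation
Version: 0.1.0
Authors@R:
    person("Open", "Contributor", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and validating epigenetic ageing clocks from
    targeted bisulphite amplicon sequencing of ribosomal DNA. Covers percent
    methylation calling from Bismark-style coverage counts, locus quality
    control, per-CpG linear screening with Holm correction and saturation-age
    extrapolation, penalized-regression (ridge/elastic net/lasso) age models
    with nested leave-one-out validation, sex-effect diagnostics, reduced-locus
    models, von Bertalanffy growth modelling in standard and Francis
    parameterisations with bootstrap confidence intervals, and a synthetic-data
    generator emulating a known-age lobster cohort design so the whole pipeline
    is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
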