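Package: rootshift
Title: Drought-Recovery Phenotyping of Rice: Water Recovery Index, GWAS
    Peak Co-Location and Root Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing shoot-versus-root investment of
    rice (Oryza sativa) during recovery from drought. Computes relative growth
    rates from shoot dry weights, per-compartment growth rates from
    longitudinal leaf-length and crown-root-number records, and the Water
    Recovery Index (WRI) that ranks genotypes from conservative to
    less-conservative recovery strategies. Also clusters genome-wide
    association peaks that co-locate across field seasons within a fixed
    genomic window and extracts candidate genes in flanking windows,
    partitions scanned root systems into S-type, L-type and axial diameter
    classes with a link analysis of lateral-root length, and provides the
    treatment-comparison statistics (one-sample t, Type II ANOVA, Tukey HSD
    with compact letters) used to report such experiments. Synthetic-data
    generators with planted, recoverable structure emulate the field and
    glasshouse designs so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    igraph,
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
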