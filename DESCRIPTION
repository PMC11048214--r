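Package: mitovar
Title: Mitochondrial Variant Filtering, Annotation and Case-Control Enrichment
Version: 0.1.0
Authors@R:
    person("mitovar", "maintainers", email = "mitovar@example.org",
           role = c("aut", "cre"))
Description: Post-variant-calling analysis of human mitochondrial DNA (mtDNA)
    and nuclear-encoded mitochondrial-gene variants in case-control cohorts.
    Provides a circular rCRS region atlas (genes, control-region hypervariable
    segments, functional domains, secondary-structure elements, homopolymeric
    tracts), heteroplasmy-aware variant retention filters, rare-variant
    prioritisation cascades (impact class, control sharing, population
    frequency, CADD), pathogenicity-predictor concordance scoring, exact and
    chi-square contingency-table enrichment tests, mtDNA copy-number estimation
    from depth ratios, and a fully parameterised synthetic-cohort generator
    for end-to-end validation without access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
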