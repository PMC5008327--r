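Package: nbmut
Title: Somatic Mutation Spectrum, Driver Prioritization and Germline
    Burden Analysis for Aggressive Neuroblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-variant-calling analysis pipeline for tumor-normal
    sequencing studies of clinically aggressive neuroblastoma: somatic
    variant filtering with per-rule audit, 96-trinucleotide-context
    mutation spectra and non-negative least-squares decomposition onto
    reference mutational signatures, dual-score (CHASM/VEST style)
    driver-gene prioritization with Benjamini-Hochberg false discovery
    control, preranked gene-set enrichment analysis over
    pathogenicity-ranked mutated genes, and a multi-cohort rare-variant
    germline burden test based on two-sided Fisher's exact tests with
    pooled-control combination. A seeded synthetic-cohort generator
    emulates every input so the full pipeline is testable without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
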