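Package: plasmascreen
Title: Contamination and Batch-Effect Screening for Low-Biomass Plasma
    Metagenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control and statistical screening of
    low-biomass plasma metagenomic sequencing experiments. Implements
    tag-aware read filtering for Sol-B primed libraries (DUST
    low-complexity scoring, paired and single-read dereplication, a
    seven-rule per-read filter with B-tail trimming), taxon count
    profiling with filtered-read normalisation, presence-overlap
    screening against plasma-free negative extraction controls,
    per-taxon group-versus-batch regression with overdispersed count
    models and Bonferroni correction, paired-read concordance audits of
    low-abundance taxon calls, exact cohort-table tests, and a synthetic
    data generator with per-read and per-taxon truth labels for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    pheatmap,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
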