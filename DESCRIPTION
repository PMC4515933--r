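Package: panelTriage
Title: Clinical Variant Prioritisation, Coverage QC and Reporting for
    Targeted Gene Panels
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the clinically bespoke layer of a diagnostic
    exome/panel analysis: four-tier variant prioritisation (Variant
    Priority Index) combined with a-priori gene categories (Gene
    Priority Index), per-sample analysis profiles, a site-local SQLite
    database of variant observations used to filter recurrent private
    variants and sequencing artefacts, three-level coverage quality
    reports (gene, exon and base-pair gap), automated per-sample QC
    gates, and deterministic curation-ready CSV outputs including an
    LOVD3-compatible export. A seeded synthetic batch generator
    produces complete test batches with machine-readable truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    DBI,
    RSQLite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
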