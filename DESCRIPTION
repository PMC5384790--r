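Package: minigene
Title: Interpretation of Splicing Reporter Minigene Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hybrid-minigene splicing assays: a model of
    splicing-reporter constructs (vector exons, cloned exons and shortened
    introns, HGVS c. coordinate anchors, RT-PCR primer sites), an event
    engine that derives transcript structures, sizes and HGVS r.
    descriptions from exon skipping, alternative splice-site use and
    partial intron retention, annotation of reading-frame status,
    premature termination codons and protein-level HGVS consequences,
    quantification of transcript ratios from capillary-electrophoresis
    peak tables, position-weight-matrix scanning for exonic splicing
    enhancers with microdeletion mapping, simulation of fragment-analysis
    data with controlled mixtures and noise, and a codified
    splicing-viewpoint clinical classification of spliceogenic variants.
    Ships a worked BRCA2 exon 17/18 reporter fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
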