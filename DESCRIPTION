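Package: apmscurate
Title: Specificity Curation and Enrichment Analysis for AP-MS Interactomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Curates affinity-purification mass-spectrometry (AP-MS)
    interactomes from peptide-spectrum-match (PSM) count tables using
    peptide-competition negative controls and a genetic bait-null control:
    spectral-count enrichment-ratio filtering, null-cell subtraction,
    reconciliation of hits across treatment conditions into a union
    interactome and a condition-independent core, contaminant-list
    (CRAPome-style) overlap reporting, and in-house hypergeometric
    over-representation analysis of the curated hit lists against GMT
    gene-set collections. Ships a ground-truthed negative-binomial
    simulator of the four-arm peptide-competition design so the whole
    pipeline can be exercised and benchmarked without raw mass-spectrometry
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
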