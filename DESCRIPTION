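Package: hippoapms
Title: AP-MS Interaction Scoring and Modular Analysis of a Pathway Interactome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for affinity-purification mass-spectrometry
    (AP-MS) interaction proteomics, built around the workflow that mapped the
    human Hippo-pathway interactome. Computes NSAF spectral-count abundances,
    a mock-control contaminant profile with top-n averaging, a control
    enrichment filter, CompPASS-style WD scores normalized by a simulated
    (permuted) data matrix quantile, profile-based rescue of sub-threshold
    interactions, uncentered-Pearson average-linkage module discovery, recall
    against reference protein-protein interaction sets, and label-free TOP3
    quantification of complexes across conditions. Includes a synthetic AP-MS
    generator with planted modular truth networks so every stage is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
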