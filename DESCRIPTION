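Package: degnet
Title: Network-Guided Differential Expression Analysis of Biologic Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative transcriptomic workflow for stratifying treatment
    response from CD4+ expression profiles: TPM normalisation and log
    transformation, per-batch location-scale adjustment, empirical-Bayes
    moderated t-statistics for differential expression, hypergeometric and
    randomization tests for gene-list overlap, expansion of seed gene lists
    over a protein-protein interaction network, hypergeometric pathway
    enrichment with Benjamini-Hochberg control and key-term weighting,
    cross-comparison pathway membership profiling, and hierarchical
    clustering / PCA separation of responder groups. Includes a synthetic
    study generator (cohort, expression with planted pathway signal, modular
    PPI network, pathway collections) so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    limma,
    mclust,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
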