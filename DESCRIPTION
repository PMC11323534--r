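Package: sulfotrace
Title: Phenotype-Guided Comparative Genomics of Sulfur Oxidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links sulfur-oxidation phenotype to gene content and
    transcriptomic response across thermoacidophilic archaea
    (Sulfolobaceae). Provides a presence/absence phenotype score over
    pangenome matrices, turbidimetric sulfate-assay reduction and
    oxidizer classification, per-species negative-binomial differential
    expression with a quasi-likelihood F-test, principal-component
    condition-axis candidate selection, cross-species homolog consensus
    with direction-of-regulation agreement, and gene gain/loss ancestral
    reconstruction on a rooted phylogeny by asymmetric Wagner parsimony.
    Includes seeded synthetic-data generators with ground-truth records
    for every stage and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    edgeR
Config/testthat/edition: 3
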