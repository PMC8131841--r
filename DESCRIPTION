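Package: mirconnect
Title: Gene-Set Overconnectivity, ddPCR Quantification and Circulating
    miRNA Biomarker Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational chain of a circulating-miRNA
    biomarker study: a hypergeometric overconnectivity test for directed
    interaction links between two gene sets against a background
    interactome, Poisson absolute quantification of droplet digital PCR
    (ddPCR) panels, a two-control differential-expression signature
    screen with Benjamini-Hochberg false discovery control, nonparametric
    group comparison and cross-validated ROC statistics, and seeded
    synthetic-data generators so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
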