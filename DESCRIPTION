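Package: pdzscan
Title: Proteome Scanning for PDZ Domain-Peptide Interactions with Support
    Vector Machines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts interactions between PDZ domains and the C-terminal
    peptides of candidate target proteins. Implements genomic-likeness
    filtering of phage-display data, generation of artificial negative
    interactions from position weight matrices, contact-map feature encoding
    of domain-peptide pairs, weighted-cost support vector machines with a
    radial basis function kernel, multi-scheme cross-validation (including
    leave-domain-out and leave-peptide-out), nearest-neighbour and PWM
    ensemble baselines, and scanning of whole proteomes for candidate
    binders. A seeded synthetic-data generator with planted binding
    specificities supports end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Biostrings,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
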