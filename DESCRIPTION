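Package: codivkit
Title: Host-Population Signal in Hominid Gut Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream statistics for detecting host-population structure in
    gut metagenome data: abundance-table construction (rarefaction, genome
    coverage filtering, TPM normalization), compositional diversity and
    differential-abundance analysis with an ALDEx-style Dirichlet Monte-Carlo
    effect size, CAZyme substrate-shift testing via centred log-ratio
    transformation with bootstrap confidence intervals, and phylosymbiosis
    quantification through PERMANOVA on patristic distances of strain and
    gene trees. Includes a synthetic-data generator with planted signal so
    every stage can be validated by recovery of known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
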