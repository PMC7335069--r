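Package: neurovuln
Title: Transcriptional Vulnerability Mapping from Morphometric Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for testing the transcriptional vulnerability model of
    neurogenetic disorders: construction of per-subject morphometric
    similarity networks (MSNs) from regional cortical features, linear-model
    change maps for gene-dosage contrasts, partial least squares (SIMPLS)
    ranking of atlas genes against anatomical change maps, median-rank
    permutation enrichment of gene sets (genome-wide, within-chromosome,
    dosage-sensitivity and rank-decile variants), weighted cell-class
    expression maps from single-cell signature sets, spherical rotation
    ("spin") spatial null models, and subject-level coupling of peripheral
    gene expression to cortical anatomy. Includes a synthetic-data generator
    that emulates the statistical structure of the required morphometric and
    regional-expression inputs with planted, configurable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
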