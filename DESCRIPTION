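Package: hotspotqtl
Title: Multi-Omic QTL Hotspot Mapping for Inbred Strain Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping expression, methylation, and
    methylation-driven expression quantitative trait loci (eQTL, mQTL,
    emQTL) in panels of fully inbred strains, and for detecting trans
    regulatory hotspots. Implements an EMMA-style linear mixed model with
    kinship correction for continuous traits, a MACAU-style binomial
    mixed model for bisulfite read counts fitted by penalized
    quasi-likelihood, 500 kb windowed hotspot detection with
    Bonferroni-controlled significance, circular-shift overlap enrichment
    against prior association loci, candidate-gene evidence scoring, and
    a gene-set correlation permutation test. A synthetic inbred-panel
    generator with planted cis effects, trans hotspots, and treatment
    contrasts makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    tools,
    utils
Suggests:
    glmmTMB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
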