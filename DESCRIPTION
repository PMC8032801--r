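Package: famflux
Title: Gene-Family Gain/Loss Dynamics and Receptor Repertoire Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolutionary dynamics of chemoreceptor
    gene families across a species phylogeny. Implements candidate gene
    mining from ranked homology-hit tables (stopping rules, bounded
    open-reading-frame completion, length filtering), fingerprint-motif
    classification of trace amine-associated receptors (TAAR) versus their
    taar-like (TARL) sister clade, placement-based clade labelling on
    reference trees, phylogeny-aware gene naming, Dollo-parsimony
    reconstruction of gene gain and loss events on a species tree, and
    repertoire/ortholog summary statistics. A birth-death gene-family
    simulator with sequence evolution and genomic embedding provides
    ground truth for every stage. Ships the published repertoire matrix of
    taar and tarl gene counts in aquatic vertebrates as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
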