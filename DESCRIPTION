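Package: eccloc
Title: Multi-Label Protein Subcellular Localization with Ensembles of
    Classifier Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the subcellular locations of eukaryotic proteins that may
    reside in more than one compartment. Features are extracted either by gene
    ontology homology transfer (the fraction of a query's filtered BLAST
    homologs annotated with each GO term) or, when no usable homolog exists, by
    a 420-dimensional dipeptide composition (amino-acid composition plus
    dipeptide fractions). Multi-label prediction uses Binary Relevance and
    Ensembles of Classifier Chains over a linear max-margin base learner, with
    per-label vote aggregation and thresholding. Includes the locative and
    exact-match jackknife evaluation protocol, a synthetic-world generator for
    fully offline testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    optparse,
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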