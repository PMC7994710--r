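Package: coevopair
Title: Mutual-Information Degeneracy in Protein Partner Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how far interface mutual information (MI) can
    resolve interaction partners between two coevolving protein families.
    Implements per-contact MI over paired multiple sequence alignments with
    pseudocount smoothing, interface contact extraction from complex
    structures, a mutation-only elitist genetic algorithm that maximises
    interface MI over the space of row pairings (with a within-species move
    set for paralogous families), mismatch-discounted true-positive rates,
    type-(i)/type-(ii) solution classification with k-nearest-neighbour
    separation, an evolutive/coevolutive MI decomposition, and a synthetic
    generator of coevolved alignment pairs with controllable coupling
    strength, similarity-cluster structure and species composition.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    class,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
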