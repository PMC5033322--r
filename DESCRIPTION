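Package: specirc
Title: Genome-Scale Species Circumscription for Closely Related Bacterial Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demarcates bacterial species within groups of highly
    phylogenetically related strains using whole-genome evidence.
    Implements fragment-based average nucleotide identity (ANIb) with
    Pearson-correlation clustering of ANI profiles, reciprocal-best-hit
    core-gene detection, concatenated core-gene (MLSA-style) distance
    phylogenies with bootstrap, binary function-repertoire clustering with
    phylogenomic/functional dendrogram comparison for ecotype detection,
    random-forest ranking of core genes as phylogenetic markers from
    gene-distance features, and single-marker PCA classification with 95%
    confidence ellipses and outclass detection. A seeded clade simulator
    generates synthetic strain sets with known species structure so every
    stage can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    randomForest,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
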