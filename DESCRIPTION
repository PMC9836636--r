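Package: motulib
Title: DNA Barcode Library Auditing and Molecular Species Delimitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing COI-5P DNA barcode reference libraries.
    Covers sequence quality control with reading-frame detection and
    stop-codon (NUMT) screening, Kimura two-parameter distances with
    pairwise deletion, neighbour-joining and UPGMA trees, molecular
    species delimitation by distance thresholds, refined single-linkage
    clustering, the single-threshold general mixed Yule-coalescent model
    and a maximum-likelihood Poisson tree process, per-species barcode-gap
    statistics, cluster-taxon discordance categories (MATCH, SPLIT, MERGE,
    MIXTURE), partition-concordance indices (match ratio, taxonomic index
    of congruence, relative taxonomic resolving power), and a coalescent
    barcode simulator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    cluster,
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
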