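Package: cpPhylo
Title: Comparative Chloroplast Phylogeography of Co-Distributed Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end comparative phylogeography from aligned chloroplast
    spacer sequences and population coordinates: haplotype recoding (indels and
    inversions as single mutations) and collapsing, haplotype and nucleotide
    diversity, ordered versus unordered differentiation (N_ST/G_ST) with a
    permutation U-test, AMOVA and a spatially constrained simulated-annealing
    search for population groupings (SAMOVA), median-joining haplotype
    networks, neutrality tests (Tajima's D, Fu's F_S), mismatch-distribution
    fitting under the sudden-expansion model with parametric-bootstrap
    goodness-of-fit and calendar dating, and climatic-niche overlap
    (Schoener's D, Hellinger I) with pooled-pseudoreplicate identity tests.
    Ships structured-coalescent and landscape generators so every estimator
    can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
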