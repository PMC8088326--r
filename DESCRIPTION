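Package: degenDesign
Title: Design and In Silico Validation of Degenerate and Spiked Codon
    Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Designs degenerate or spiked (variable nucleotide ratio)
    DNA templates encoding combinatorial protein libraries whose overall
    amino-acid composition approximates a user-specified target
    distribution at a given length. Codons are modelled as 12-tuples of
    per-position nucleotide fractions; a stochastic local search over
    codon multisets minimises the distance between the encoded
    amino-acid mixture and the target. Includes codon algebra over the
    3375 base-codon supports with IUPAC interconversion, pre-selection
    filters (forbidden codons, stop removal, codon-usage and degeneracy
    caps), a benchmark harness, and an in silico validation layer that
    samples concrete sequences from a design and reports composition
    deviations, library diversity, per-position nucleotide frequencies
    and expected molecular-weight distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
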