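Package: rnadivnet
Title: Divergence Profiling and Bayesian Network Analysis of Structured RNA Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates informative positions in gapped alignments of structured
    RNAs (typically tRNAs) by two complementary routes. A per-column
    Jensen-Shannon divergence statistic scores how strongly the nucleotide
    distribution within a sequence subclass (amino-acid class by domain of
    life) departs from the pooled distribution, calibrated against a
    permutation null obtained by shuffling class labels. Discrete Bayesian
    network structure learning over alignment columns, with multinomial local
    models and an MDL (penalized likelihood) score optimized by greedy
    hill-climbing with random restarts, exposes intra-molecule dependencies
    such as stem pairings and tertiary contacts. Includes a synthetic
    alignment generator with planted stems, determinants and gap regions for
    calibration, classification of candidate identity determinants against a
    reference list, and TSV/DOT exports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
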