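Package: rdclosest
Title: Closest String and Closest Substring Search via Rank Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank distance (the Spearman footrule extended to arbitrary
    strings through occurrence-indexed annotation) together with Hamming and
    Levenshtein comparators, and genetic algorithms that approximate the
    NP-hard closest string and closest substring problems under any of the
    three metrics. The closest string search encodes candidates as
    permutations of annotated-symbol ranks and evolves them with three
    order-based crossovers, swap mutation and half-normal rank selection;
    the closest substring search evolves fixed-length nucleotide strings
    with one-point crossover and point mutation, scoring candidates against
    every sliding window of the inputs with a memoised fitness. Includes
    FASTA prefix input, experiment configs, per-generation traces and
    deterministic synthetic-instance generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
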