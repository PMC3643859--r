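Package: natpipe
Title: Discovery and Small RNA Profiling of Natural Antisense Transcript Pairs
Version: 0.1.0
Authors@R: person("natpipe", "developers", role = c("aut", "cre"),
    email = "natpipe@example.org")
Description: Predicts natural antisense transcript (NAT) pairs from a
    transcript set by ungapped antisense seed-and-extend alignment with
    Karlin-Altschul E-values, classifies pairs as cis or trans from gene
    coordinates (convergent, divergent, enclosed), profiles NAT-derived
    small RNAs (strand bias, chi-squared enrichment of small RNA loci in
    the overlap region), calls nat-siRNA targets from degradome 5' tags
    with a position-specific mismatch rule, screens NAT transcripts for
    pre-miRNA-like stem-loops with a built-in base-pair-maximisation
    folder, and ships a seeded synthetic-data generator with a
    ground-truth manifest so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
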