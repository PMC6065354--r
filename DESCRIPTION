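Package: stopkit
Title: Design and Quantification of Stop-Codon-Introducing CRISPR Base Edits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for cytidine-deaminase (Target-AID style) base-editing
    experiments that introduce premature stop codons. Scans coding sequences
    for cytosines whose C>T conversion in the PAM-relative editing window
    creates a stop codon and emits scored sgRNA designs; enumerates candidate
    off-target sites under canonical and non-canonical PAMs with bounded
    mismatches; aligns amplicon deep-sequencing reads with explicit
    semi-global dynamic programming, applies coverage/count/frequency variant
    filters and tabulates the PAM-relative mutation spectrum, indel frequency
    and substitution:indel ratio; designs allele-specific PCR (ARMS) primer
    sets with an engineered 3'-proximal mismatch and verifies them by
    in-silico PCR; tallies offspring genotypes and tests Mendelian
    segregation; and simulates amplicon read sets and multi-generation
    crosses so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
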