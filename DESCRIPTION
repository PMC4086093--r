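Package: afdist
Title: Alignment-Free Sequence Distances from Spaced Words and
    k-Mismatch Common Substrings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates pairwise distances between unaligned DNA or protein
    sequences with two alignment-free methods: relative frequencies of
    spaced words defined by match/don't-care patterns (compared with the
    Euclidean or Jensen-Shannon distance and averaged over a pattern set),
    and the k-mismatch average common substring (kmacs) distance based on
    per-position longest matches with up to k Hamming mismatches. Reads
    FASTA input, writes Phylip distance matrices and Neighbour-Joining
    trees in Newick format, and includes a sequence simulator for
    benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
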