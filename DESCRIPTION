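Package: stringassembly
Title: Assembly Indices, Pathways and the Assembly Observable for Strings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact computation of the assembly index of a string -- the
    minimal number of recursive concatenation joins needed to build it from
    its single characters, with reuse of previously built fragments -- via a
    memoized iterative-deepening branch-and-bound search, together with
    witnessing assembly pathways, a brute-force oracle for validation, and
    the shortest-addition-chain solver for single-letter strings.  Computes
    the ensemble Assembly observable combining assembly indices with copy
    numbers, and the baseline complexity measures it is contrasted with:
    Shannon entropy, deterministic Huffman coding, and LZW compression.
    Includes the scaling and permutation-correlation experiments comparing
    the assembly index against compression-based measures, seeded fixture
    generation, plain-text and FASTA input, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
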