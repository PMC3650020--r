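Package: seqrank
Title: Google Matrix and PageRank Analysis of DNA Word-Transition Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the Markov transition matrix between fixed-length words
    (k-mers) of a DNA sequence, forms the corresponding Google matrix
    G = alpha*S + (1-alpha)/N, and analyzes it: PageRank and CheiRank
    vectors, the full eigenvalue spectrum and spectral gap, eigenvector
    localization (inverse participation ratio), power-law distributions of
    matrix elements and of ingoing element sums, and a PageRank-proximity
    correlator for the statistical comparison of two sequences. Includes
    seeded synthetic-sequence generators (i.i.d. letters, word-level Markov
    chains, planted Zipf stationary laws, shuffled-element null models) so
    that every stage of the pipeline can be exercised and validated without
    external genome data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
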