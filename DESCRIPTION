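Package: sparsesa
Title: Direct Construction of Sparse Suffix Arrays via K-Mer Bit-Packing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sparse suffix arrays (SSAs) of nucleotide, protein or
    other small-alphabet texts directly, without first constructing the full
    suffix array. Each non-overlapping k-mer of the text is bit-packed into a
    single machine word using an order-preserving minimal-bit character
    encoding, and the resulting shortened integer sequence is suffix-sorted
    with an induced-sorting (SA-IS) algorithm, yielding the SSA in one pass.
    Includes exact pattern search over the SSA via shifted queries with
    in-text verification, a subsampling baseline for cross-validation, a
    divisor strategy for large sparseness factors, FASTA concatenation with a
    configurable separator, and a binary index format with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
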