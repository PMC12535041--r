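# Shared fixtures and independent oracles for the test suite.

# Pool of distinct single characters for random alphabets (byte order is
# ascending within the pool's sorted form).
char_pool <- c(LETTERS, letters, as.character(0:9), "-", "*")

# Draw one element uniformly from a vector (safe for length-1 vectors,
# unlike sample(x, 1)).
pick <- function(v) v[sample.int(length(v), 1)]

# Random text of length n over the first sigma characters of the pool.
rand_text <- function(sigma, n) {
  paste(sample(char_pool[seq_len(sigma)], n, replace = TRUE), collapse = "")
}

# Draw a (sigma, k) pair jointly feasible for direct construction with
# dense buckets: bits_for_alphabet(sigma) * k <= max_bits.
rand_sigma_k <- function(sigma_range = 2:25, k_range = 1:8, max_bits = 24) {
  sigma <- sample(sigma_range, 1)
  feasible <- k_range[bits_for_alphabet(sigma) * k_range <= max_bits]
  list(sigma = sigma, k = pick(feasible))
}

# Full suffix array of a character text by brute force: radix string sort
# of all suffixes (C-locale byte order), 0-based.
oracle_char_sa <- function(text) {
  n <- nchar(text)
  order(substring(text, seq_len(n)), method = "radix") - 1L
}

# All occurrences of a pattern by an established exact matcher
# (overlapping), 0-based; independent of the package's search path.
oracle_scan <- function(text, pattern) {
  hits <- Biostrings::matchPattern(Biostrings::BString(pattern),
                                   Biostrings::BString(text))
  sort(as.numeric(Biostrings::start(hits)) - 1)
}

# Byte-order (C-locale) string comparison: -1 / 0 / 1.
cmp_bytes <- function(x, y) {
  if (identical(x, y)) return(0L)
  if (identical(sort(c(x, y), method = "radix")[1], x)) -1L else 1L
}

# Write a FASTA file; seqs is a named character vector.
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}
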