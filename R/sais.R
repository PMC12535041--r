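# Suffix sorting of integer sequences: SA-IS (the induced-sorting
# algorithm behind Libsais) with a brute-force oracle for verification.

# Bucket-count arrays are allocated dense, sized exactly by the alphabet
# upper bound; 2^26 words is the supported ceiling (larger transformed
# alphabets should use the divisor strategy).
.max_bucket_bits <- 26L

#' Suffix array of an integer sequence by induced sorting (SA-IS)
#'
#' Computes the suffix array of `seq` in linear time in
#' `length(seq) + alphabet_upper_bound`, using the induced-sorting
#' algorithm (L/S type classification, recursive LMS-substring naming,
#' induction from per-symbol bucket arrays). The bucket arrays are sized
#' exactly `alphabet_upper_bound`, so for packed texts memory scales with
#' the transformed alphabet size sigma^k.
#'
#' The last element of `seq` must be its unique minimum (a terminator);
#' packed texts from [pack_text()] satisfy this by construction.
#'
#' @param seq Numeric vector of non-negative integers, non-empty; the
#'   last element is the unique minimum.
#' @param alphabet_upper_bound Exclusive upper bound on the values of
#'   `seq` (at most 2^26).
#' @return Integer vector of 0-based suffix start positions, a
#'   permutation of `0:(length(seq) - 1)` in lexicographic suffix order.
#' @examples
#' sais(c(9, 13, 13, 0), 16)  # 3 0 2 1
#' @seealso [naive_suffix_array()] for the brute-force oracle.
#' @export
sais <- function(seq, alphabet_upper_bound) {
  seq <- as.numeric(seq)
  m <- length(seq)
  if (m == 0L) stop("empty sequence")
  if (anyNA(seq) || any(seq != floor(seq)) || any(seq < 0))
    stop("sequence elements must be non-negative integers")
  bound <- as.numeric(alphabet_upper_bound)
  stopifnot(length(bound) == 1L, !is.na(bound), bound >= 1)
  if (bound > 2^.max_bucket_bits) {
    stop(sprintf(paste0("alphabet upper bound %.0f exceeds the supported ",
                        "bucket size 2^%d; use build_with_divisor() for ",
                        "large sparseness factors"),
                 bound, .max_bucket_bits))
  }
  if (any(seq >= bound))
    stop("sequence element >= alphabet upper bound")
  mn <- min(seq)
  if (seq[m] != mn || sum(seq == mn) != 1L)
    stop("missing unique terminator: last element must be the unique minimum")
  sa <- sais_cpp(seq, bound)
  # words allocated on this path: input, suffix array, bucket counts
  attr(sa, "words") <- c(input = m, sa = m, buckets = bound)
  sa
}

#' Suffix array by brute force (testing oracle)
#'
#' Sorts all suffixes of `seq` by direct lexicographic comparison,
#' independent of the induced-sorting path: each element is rendered as a
#' fixed-width decimal string and the suffix strings are radix-sorted. A
#' shorter suffix that is a prefix of a longer one sorts first, so no
#' terminator is required.
#'
#' @param seq Numeric vector of non-negative integers (< 2^53), non-empty.
#' @return Integer vector of 0-based positions in lexicographic suffix
#'   order.
#' @examples
#' naive_suffix_array(c(0, 0, 0))  # 2 1 0
#' @export
naive_suffix_array <- function(seq) {
  seq <- as.numeric(seq)
  m <- length(seq)
  if (m == 0L) stop("empty sequence")
  if (anyNA(seq) || any(seq != floor(seq)) || any(seq < 0))
    stop("sequence elements must be non-negative integers")
  # 17 decimal digits cover all exactly-representable doubles < 2^53
  digits <- sprintf("%017.0f", seq)
  full <- paste(digits, collapse = "")
  suffixes <- substring(full, (seq_len(m) - 1L) * 17L + 1L)
  order(suffixes, method = "radix") - 1L
}
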