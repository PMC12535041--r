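# k-mer bit-packing: the order-preserving text transformation that makes
# direct SSA construction possible. Packed block values are stored as R
# doubles, which represent integers exactly up to 2^53; the packed width
# b*k is capped accordingly.

.max_pack_bits <- 53L

#' Pack an encoded text into non-overlapping k-mer blocks
#'
#' Groups the code sequence into consecutive non-overlapping k-mers and
#' bit-packs each into one unsigned integer, leftmost character in the
#' most significant bits, so that integer order of blocks equals
#' lexicographic order of k-mers. Conceptually one sentinel (code 0) is
#' appended after the text and the tail is right-padded with further
#' sentinels so that the packed sequence ends in exactly one all-zero
#' block (`ceiling(n / k) + 1` blocks in total): a unique minimal
#' terminator, which induced sorting requires, and which makes padded
#' tails compare smaller than any real suffix.
#'
#' The transformed text has about `ceiling(n / k)` blocks, reducing the
#' input length for suffix sorting by a factor k, while the transformed
#' alphabet grows to `2^(bits_per_symbol * k)` (see
#' [packed_alphabet_size()]).
#'
#' @param encoded An `encoded_text` from [encode_text()].
#' @param k Sparseness factor (positive integer);
#'   `bits_per_symbol * k` must not exceed 53.
#' @return An object of class `packed_text`: list with `blocks` (numeric
#'   vector of packed values), `k`, `bits_per_symbol`, `word_bits` (the
#'   smallest of 8/16/32/64 holding `bits_per_symbol * k`), `source_n`
#'   (original text length) and `alphabet`.
#' @examples
#' enc <- encode_text("ACGT", build_alphabet("ACGT"))
#' pack_text(enc, 2)$blocks  # 10 28 0: (1*8+2), (3*8+4), terminator
#' @export
pack_text <- function(encoded, k) {
  stopifnot(inherits(encoded, "encoded_text"))
  k <- .check_k(k)
  b <- encoded$alphabet$bits_per_symbol
  .check_pack_width(b, k)
  n <- encoded$n
  # real characters plus sentinel padding to whole blocks, always ending
  # in one all-zero block: the unique minimal terminator SA-IS needs
  n_blocks <- as.integer(ceiling(n / k)) + 1L
  padded <- c(encoded$codes, integer(n_blocks * k - n))
  weights <- 2^(b * ((k - 1L):0L))
  blocks <- as.numeric(colSums(matrix(padded, nrow = k) * weights))
  bk <- b * k
  structure(
    list(blocks = blocks,
         k = k,
         bits_per_symbol = b,
         word_bits = .word_bits(bk),
         source_n = n,
         alphabet = encoded$alphabet),
    class = "packed_text"
  )
}

#' Size of the transformed (packed) alphabet
#'
#' The exclusive upper bound on packed block values, `2^(bits_per_symbol
#' * k)`. This is the bucket-count driver for induced sorting: bucket
#' memory grows with the transformed alphabet, which is why very large k
#' should go through [build_with_divisor()] instead.
#'
#' @param alphabet An `ssa_alphabet`.
#' @param k Sparseness factor.
#' @return A numeric scalar, `2^(bits_per_symbol * k)`.
#' @examples
#' packed_alphabet_size(build_alphabet("ACGT"), 2)  # 64
#' @export
packed_alphabet_size <- function(alphabet, k) {
  stopifnot(inherits(alphabet, "ssa_alphabet"))
  k <- .check_k(k)
  .check_pack_width(alphabet$bits_per_symbol, k)
  2^(alphabet$bits_per_symbol * k)
}

.check_k <- function(k) {
  stopifnot(length(k) == 1L, is.numeric(k), !is.na(k), k >= 1, k == floor(k))
  as.integer(k)
}

.check_pack_width <- function(b, k) {
  if (b * k > .max_pack_bits) {
    stop(sprintf(paste0("packed k-mer needs %d bits, exceeding the %d-bit ",
                        "limit of exact double-precision integers; reduce k ",
                        "or use build_with_divisor()"),
                 b * k, .max_pack_bits))
  }
  invisible(TRUE)
}

.word_bits <- function(bk) {
  w <- c(8L, 16L, 32L, 64L)
  w[which(w >= bk)[1L]]
}

#' @export
print.packed_text <- function(x, ...) {
  cat(sprintf("packed_text: %d blocks (k = %d, %d bits/block in %d-bit words) from n = %d\n",
              length(x$blocks), x$k, x$bits_per_symbol * x$k, x$word_bits,
              x$source_n))
  invisible(x)
}
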