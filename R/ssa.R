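# Sparse suffix array construction: the direct route (pack + SA-IS), the
# classical subsampling baseline, and the divisor strategy for large k.

new_sparse_suffix_array <- function(positions, k, n, alphabet) {
  structure(list(positions = as.numeric(positions), k = as.integer(k),
                 n = as.numeric(n), alphabet = alphabet),
            class = "sparse_suffix_array")
}

#' @export
print.sparse_suffix_array <- function(x, ...) {
  cat(sprintf("sparse_suffix_array: %d entries (k = %d, n = %.0f, sigma = %d)\n",
              length(x$positions), x$k, x$n, x$alphabet$size))
  invisible(x)
}

#' @export
length.sparse_suffix_array <- function(x) length(x$positions)

#' Build a sparse suffix array directly via k-mer packing
#'
#' The direct construction route: encode the text with the
#' order-preserving minimal-bit alphabet, bit-pack non-overlapping k-mers
#' into single integers ([pack_text()]), suffix-sort the packed sequence
#' with induced sorting ([sais()]), multiply each packed position by k and
#' drop entries pointing into the sentinel-padded tail. Because the
#' packing preserves lexicographic order between suffixes starting at
#' multiples of k, the result is identical, entry for entry, to
#' subsampling the full suffix array ([build_sampled()]) -- but the full
#' array is never built: the sorter's input is k times shorter.
#'
#' The transformed alphabet has `2^(bits_per_symbol * k)` symbols, which
#' drives induced sorting's bucket memory; when that exceeds the
#' supported bucket size, use [build_with_divisor()].
#'
#' @param text A single non-empty character string.
#' @param k Sparseness factor (positive integer).
#' @return An object of class `sparse_suffix_array`: list with
#'   `positions` (0-based suffix starts, all divisible by k, in
#'   lexicographic suffix order, `ceiling(n / k)` of them), `k`, `n` and
#'   `alphabet`. Attribute `words` records the words allocated by the
#'   sorting step (input + suffix array + bucket counts).
#' @examples
#' build_direct("banana", 2)$positions  # 0 4 2
#' @export
build_direct <- function(text, k) {
  k <- .check_k(k)
  alphabet <- build_alphabet(text)
  enc <- encode_text(text, alphabet)
  packed <- pack_text(enc, k)
  bound <- packed_alphabet_size(alphabet, k)
  if (bound > 2^.max_bucket_bits) {
    stop(sprintf(paste0("transformed alphabet 2^%d exceeds the supported ",
                        "bucket size 2^%d; use build_with_divisor() with a ",
                        "divisor of k = %d"),
                 alphabet$bits_per_symbol * k, .max_bucket_bits, k))
  }
  sa <- sais(packed$blocks, bound)
  pos <- as.numeric(sa) * k
  ssa <- new_sparse_suffix_array(pos[pos < enc$n], k, enc$n, alphabet)
  attr(ssa, "words") <- attr(sa, "words")
  ssa
}

#' Build a sparse suffix array by subsampling the full suffix array
#'
#' The classical baseline: construct the full suffix array of the text
#' (over the character codes, with a sentinel terminator), drop the
#' sentinel entry, and keep only positions divisible by k. Peak memory is
#' that of full suffix array construction, which is exactly what
#' [build_direct()] avoids; this route serves as the reference the direct
#' route is validated against.
#'
#' @inheritParams build_direct
#' @return A `sparse_suffix_array`; see [build_direct()].
#' @examples
#' build_sampled("banana", 1)$positions  # 5 3 1 0 4 2: the full SA
#' @export
build_sampled <- function(text, k) {
  k <- .check_k(k)
  alphabet <- build_alphabet(text)
  enc <- encode_text(text, alphabet)
  seq <- c(enc$codes, 0)
  sa <- sais(seq, alphabet$size + 1)
  pos <- as.numeric(sa)
  pos <- pos[pos < enc$n]          # drop the sentinel suffix
  ssa <- new_sparse_suffix_array(pos[pos %% k == 0], k, enc$n, alphabet)
  attr(ssa, "words") <- attr(sa, "words")
  ssa
}

#' Build a sparse suffix array via a divisor of the sparseness factor
#'
#' For large k the transformed alphabet `2^(bits_per_symbol * k)` makes
#' direct construction impractical. Instead, construct directly at a
#' divisor d of k (keeping the transformed alphabet small) and subsample
#' the result to positions divisible by k. The output is identical to
#' `build_direct(text, k)` whenever the latter is feasible.
#'
#' @inheritParams build_direct
#' @param d A divisor of `k` used during construction.
#' @return A `sparse_suffix_array` with sparseness `k`.
#' @examples
#' build_with_divisor("banana", 4, 2)$positions  # 0 4
#' @export
build_with_divisor <- function(text, k, d) {
  k <- .check_k(k)
  d <- .check_k(d)
  if (k %% d != 0L) stop(sprintf("d must divide k (got k = %d, d = %d)", k, d))
  ssa_d <- build_direct(text, d)
  ssa <- new_sparse_suffix_array(ssa_d$positions[ssa_d$positions %% k == 0],
                                 k, ssa_d$n, ssa_d$alphabet)
  attr(ssa, "words") <- attr(ssa_d, "words")
  ssa
}

#' Memory-footprint model of the two construction routes
#'
#' Words allocated by the suffix-sorting step of each route, matching the
#' `words` attribute the builders attach: the sorter's input sequence,
#' the suffix array, and the dense bucket-count array sized by the
#' alphabet upper bound. For the direct route the input has
#' `~ceiling(n / k)` blocks but buckets grow as `2^(bits_per_symbol *
#' k)`; for the sampled route the input has `n + 1` codes and `sigma + 1`
#' buckets regardless of k. The crossover between the two is the
#' practical upper limit on k for direct construction.
#'
#' @param n Text length in characters.
#' @param sigma Alphabet size (distinct characters).
#' @param k Sparseness factor.
#' @param method `"direct"` or `"sampled"`.
#' @return Total words as a numeric scalar.
#' @export
construction_footprint <- function(n, sigma, k, method = c("direct", "sampled")) {
  method <- match.arg(method)
  k <- .check_k(k)
  b <- bits_for_alphabet(sigma)
  if (method == "direct") {
    m <- if ((n + 1) %% k == 0) (n + 1) / k + 1 else ceiling((n + 1) / k)
    m + m + 2^(b * k)
  } else {
    (n + 1) + (n + 1) + (sigma + 1)
  }
}
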