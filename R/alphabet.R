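#' Build an order-preserving minimal-bit alphabet from a text
#'
#' Assigns each distinct character of `text` an unsigned integer code such
#' that code order equals the native (byte) order of the characters:
#' codes run 1..sigma in strictly ascending character order. Code 0 is
#' reserved as the sentinel/padding symbol and is never produced for an
#' input character, so padded k-mer tails compare strictly smaller than
#' any block containing a real character. The number of bits per symbol is
#' the smallest b with 2^b >= sigma + 1 (sentinel included): the canonical
#' 20-letter amino-acid alphabet therefore needs 5 bits per character.
#'
#' Case is significant (`'a' != 'A'`); no normalisation is applied.
#'
#' @param text A single character string (non-empty).
#' @param max_symbols Maximum number of distinct characters allowed
#'   (default 64).
#' @return An object of class `ssa_alphabet`: a list with `symbols`
#'   (characters in code order), `codes` (named integer vector, codes of
#'   `symbols`), `bits_per_symbol`, `sentinel_code` (always 0) and
#'   `size` (sigma, the number of distinct symbols).
#' @examples
#' a <- build_alphabet("ACGT")
#' a$codes            # A=1, C=2, G=3, T=4
#' a$bits_per_symbol  # 3 (must also hold the sentinel: 2^3 >= 5)
#' @export
build_alphabet <- function(text, max_symbols = 64L) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || nchar(text) == 0L) stop("empty input")
  bytes <- sort(unique(as.integer(charToRaw(text))))
  if (length(bytes) > max_symbols) {
    stop(sprintf("alphabet has %d distinct symbols; the limit is %d",
                 length(bytes), max_symbols))
  }
  .alphabet_from_bytes(bytes)
}

# Construct an ssa_alphabet from sorted distinct byte values.
.alphabet_from_bytes <- function(bytes) {
  sigma <- length(bytes)
  symbols <- vapply(bytes, function(b) rawToChar(as.raw(b)), character(1))
  codes <- seq_len(sigma)
  names(codes) <- symbols
  lookup <- integer(256L)          # byte value + 1 -> code, 0 = absent
  lookup[bytes + 1L] <- codes
  structure(
    list(symbols = symbols,
         codes = codes,
         bits_per_symbol = bits_for_alphabet(sigma),
         sentinel_code = 0L,
         size = sigma,
         lookup = lookup),
    class = "ssa_alphabet"
  )
}

#' Bits needed per symbol for an alphabet of a given size
#'
#' The smallest b with `2^b >= sigma + 1`; the `+ 1` accounts for the
#' reserved sentinel code 0.
#'
#' @param sigma Number of distinct real symbols (positive integer).
#' @return Integer number of bits.
#' @examples
#' bits_for_alphabet(20)  # 5: amino-acid alphabet
#' @export
bits_for_alphabet <- function(sigma) {
  stopifnot(sigma >= 1)
  as.integer(ceiling(log2(sigma + 1)))
}

#' @export
print.ssa_alphabet <- function(x, ...) {
  cat(sprintf("ssa_alphabet: %d symbols [%s], %d bits/symbol (code 0 = sentinel)\n",
              x$size, paste(x$symbols, collapse = ""), x$bits_per_symbol))
  invisible(x)
}

#' Encode a text into integer codes
#'
#' Maps each character of `text` to its alphabet code (1..sigma). Fails if
#' a character is absent from the alphabet, reporting the character and
#' its 0-based position.
#'
#' @param text A single character string.
#' @param alphabet An `ssa_alphabet`, typically from [build_alphabet()].
#' @return An object of class `encoded_text`: list with `codes` (integer
#'   vector of length `n`, values in 1..sigma), `n` (text length) and
#'   `alphabet`.
#' @examples
#' enc <- encode_text("banana", build_alphabet("banana"))
#' enc$codes  # 2 1 3 1 3 1
#' @export
encode_text <- function(text, alphabet) {
  stopifnot(is.character(text), length(text) == 1L,
            inherits(alphabet, "ssa_alphabet"))
  if (nchar(text) == 0L) stop("empty input")
  bytes <- as.integer(charToRaw(text))
  codes <- alphabet$lookup[bytes + 1L]
  bad <- which(codes == 0L)
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf("character '%s' at position %d (0-based) is not in the alphabet",
                 rawToChar(as.raw(bytes[i])), i - 1L))
  }
  structure(list(codes = codes, n = length(codes), alphabet = alphabet),
            class = "encoded_text")
}

#' Decode integer codes back to text
#'
#' Inverse of [encode_text()]; `decode_text(encode_text(x, a))` is `x`.
#'
#' @param encoded An `encoded_text`.
#' @return A single character string.
#' @export
decode_text <- function(encoded) {
  stopifnot(inherits(encoded, "encoded_text"))
  paste(encoded$alphabet$symbols[encoded$codes], collapse = "")
}

#' @export
print.encoded_text <- function(x, ...) {
  cat(sprintf("encoded_text: n = %d over %d symbols\n", x$n, x$alphabet$size))
  invisible(x)
}
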