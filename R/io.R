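# FASTA concatenation, the SSAX binary index format, and synthetic text
# generation.

#' Read a FASTA file and concatenate its records
#'
#' Joins all record sequences in file order with a single separator
#' character between consecutive records (no leading or trailing
#' separator), recording the 0-based positions of the separators. This
#' mirrors the standard preparation of protein databases for suffix-array
#' indexing, where all sequences are concatenated with a dash.
#'
#' @param fasta Path to a FASTA file.
#' @param separator A single character, not occurring in any sequence
#'   (default `"-"`).
#' @return An object of class `concatenated_text`: list with `text` (the
#'   joined string), `boundaries` (0-based separator positions),
#'   `separator` and `ids` (record identifiers in file order).
#' @export
read_and_concatenate <- function(fasta, separator = "-") {
  stopifnot(is.character(separator), length(separator) == 1L,
            nchar(separator) == 1L)
  seqs <- Biostrings::readBStringSet(fasta)
  if (length(seqs) == 0L) stop("FASTA file contains no records")
  strings <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(strings))
  offending <- which(vapply(strings, grepl, logical(1),
                            pattern = separator, fixed = TRUE))
  if (length(offending)) {
    stop(sprintf("separator '%s' occurs inside record '%s'",
                 separator, ids[offending[1L]]))
  }
  widths <- nchar(strings)
  boundaries <- if (length(strings) > 1L)
    cumsum(widths[-length(widths)] + 1L) - 1L else integer(0)
  structure(list(text = paste(strings, collapse = separator),
                 boundaries = as.numeric(boundaries),
                 separator = separator,
                 ids = ids),
            class = "concatenated_text")
}

#' @export
print.concatenated_text <- function(x, ...) {
  cat(sprintf("concatenated_text: %d records, %d characters, separator '%s'\n",
              length(x$ids), nchar(x$text), x$separator))
  invisible(x)
}

#' Map match positions to FASTA records
#'
#' Given 0-based positions in a concatenated text, returns the 1-based
#' index of the record each position falls in (`NA` for positions that
#' are separator characters).
#'
#' @param concat A `concatenated_text`.
#' @param positions Numeric vector of 0-based positions.
#' @return Integer vector of record indices; use `concat$ids` to recover
#'   identifiers.
#' @export
locate_record <- function(concat, positions) {
  stopifnot(inherits(concat, "concatenated_text"))
  idx <- findInterval(positions, c(-1, concat$boundaries)) # record number
  idx[positions %in% concat$boundaries] <- NA_integer_
  as.integer(idx)
}

# ---- SSAX binary index format -------------------------------------------
# magic "SSAX" | version u8 | k u32 | n u64 | word_bits u8 | sigma u8 |
# sigma symbol bytes | n_positions u64 | positions u64 each |
# checksum u32 (byte sum of the position payload mod 2^32).
# All integers little-endian.

.u_bytes <- function(x, nbytes) {
  b <- outer(as.numeric(x), 256^(0:(nbytes - 1L)),
             function(v, d) (v %/% d) %% 256)
  as.raw(as.vector(t(b)))
}

.u_value <- function(raw, nbytes) {
  m <- matrix(as.numeric(raw), nrow = nbytes)
  as.numeric(colSums(m * 256^(0:(nbytes - 1L))))
}

#' Serialize a sparse suffix array to the SSAX binary format
#'
#' Writes magic bytes, format version, k, n, the word size, the alphabet
#' (symbols in code order), the positions as 64-bit little-endian
#' unsigned integers, and a checksum of the position payload.
#' [load_index()] restores the SSA bit-for-bit.
#'
#' @param ssa A `sparse_suffix_array`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
save_index <- function(ssa, path) {
  stopifnot(inherits(ssa, "sparse_suffix_array"))
  payload <- .u_bytes(ssa$positions, 8L)
  stream <- c(charToRaw("SSAX"),
              as.raw(1L),                              # version
              .u_bytes(ssa$k, 4L),
              .u_bytes(ssa$n, 8L),
              as.raw(64L),                             # position word bits
              as.raw(ssa$alphabet$size),
              charToRaw(paste(ssa$alphabet$symbols, collapse = "")),
              .u_bytes(length(ssa$positions), 8L),
              payload,
              .u_bytes(sum(as.numeric(payload)) %% 2^32, 4L))
  writeBin(stream, path)
  invisible(path)
}

#' Load a sparse suffix array from an SSAX index file
#'
#' @param path Path to a file written by [save_index()].
#' @return A `sparse_suffix_array`.
#' @export
load_index <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  take <- function(offset, len) {
    if (offset + len - 1L > length(raw)) stop("unexpected end of index")
    raw[offset:(offset + len - 1L)]
  }
  if (length(raw) < 4L || !identical(take(1L, 4L), charToRaw("SSAX")))
    stop("not a sparsesa index (bad magic bytes)")
  version <- as.integer(take(5L, 1L))
  if (version != 1L) stop(sprintf("unsupported index version %d", version))
  k <- .u_value(take(6L, 4L), 4L)
  n <- .u_value(take(10L, 8L), 8L)
  word_bits <- as.integer(take(18L, 1L))
  if (word_bits != 64L) stop(sprintf("unsupported word size %d", word_bits))
  sigma <- as.integer(take(19L, 1L))
  symbols_raw <- take(20L, sigma)
  off <- 20L + sigma
  npos <- .u_value(take(off, 8L), 8L)
  off <- off + 8L
  payload <- take(off, 8L * npos)
  off <- off + 8L * npos
  checksum <- .u_value(take(off, 4L), 4L)
  if (off + 4L - 1L != length(raw)) stop("unexpected end of index")
  if (sum(as.numeric(payload)) %% 2^32 != checksum)
    stop("index checksum mismatch")
  positions <- if (npos > 0) .u_value(payload, 8L) else numeric(0)
  new_sparse_suffix_array(positions, k, n,
                          .alphabet_from_bytes(as.integer(symbols_raw)))
}

#' Generate a synthetic uniform random text
#'
#' Characters drawn i.i.d. uniformly from the given alphabet;
#' deterministic for a given seed. Stands in for real nucleotide or
#' protein datasets in tests and examples; the global RNG state is left
#' untouched.
#'
#' @param alphabet Either a single string of symbols (e.g. `"ACGT"`) or a
#'   character vector of single characters.
#' @param length Text length (positive integer).
#' @param seed Integer seed.
#' @return A single character string of the requested length.
#' @examples
#' generate_synthetic("ACGT", 12, seed = 1)
#' @export
generate_synthetic <- function(alphabet, length, seed) {
  stopifnot(length >= 1)
  symbols <- if (length(alphabet) == 1L && nchar(alphabet[1L]) > 1L)
    strsplit(alphabet, "")[[1L]] else as.character(alphabet)
  stopifnot(length(symbols) >= 1L, all(nchar(symbols) == 1L))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  paste(sample(symbols, length, replace = TRUE), collapse = "")
}
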