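# Exact pattern search over a sparse suffix array: binary-searched
# suffix ranges plus k shifted queries with in-text verification.

# Compare the suffix of tb (integer byte vector) starting at 0-based pos,
# truncated to length(qb), against qb: -1 / 0 / 1.
.cmp_suffix_query <- function(tb, pos, qb) {
  n <- length(tb)
  m <- length(qb)
  avail <- min(m, n - pos)
  if (avail > 0L) {
    s <- tb[(pos + 1L):(pos + avail)]
    d <- which(s != qb[seq_len(avail)])
    if (length(d)) {
      i <- d[1L]
      return(if (s[i] < qb[i]) -1L else 1L)
    }
  }
  if (avail < m) -1L else 0L
}

# Half-open [lo, hi) (0-based) over positions of the sampled suffixes
# having qb as a prefix. Byte-wise comparisons against the text.
.suffix_range_raw <- function(positions, tb, qb) {
  np <- length(positions)
  lo <- 0L; hi <- np
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (.cmp_suffix_query(tb, positions[mid + 1L], qb) < 0L) lo <- mid + 1L
    else hi <- mid
  }
  first <- lo
  hi <- np
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (.cmp_suffix_query(tb, positions[mid + 1L], qb) <= 0L) lo <- mid + 1L
    else hi <- mid
  }
  c(first, lo)
}

#' Range of sampled suffixes starting with a query
#'
#' Binary search over the sparse suffix array for the half-open index
#' range `[lo, hi)` (0-based, over `ssa$positions`) of sampled suffixes
#' that have `query` as a prefix. Comparisons are performed
#' character-wise (byte order) against the original text. An empty range
#' (`lo == hi`) means no sampled suffix starts with the query.
#'
#' @param ssa A `sparse_suffix_array` built from `text`.
#' @param text The original text the SSA indexes.
#' @param query A non-empty character string.
#' @return Integer vector `c(lo, hi)`, a 0-based half-open range.
#' @examples
#' ssa <- build_direct("banana", 2)
#' suffix_range(ssa, "banana", "na")  # 1 3: sampled suffixes at 4 and 2
#' @export
suffix_range <- function(ssa, text, query) {
  stopifnot(inherits(ssa, "sparse_suffix_array"),
            is.character(text), length(text) == 1L,
            is.character(query), length(query) == 1L)
  if (nchar(query) == 0L) stop("empty query")
  .suffix_range_raw(ssa$positions,
                    as.integer(charToRaw(text)),
                    as.integer(charToRaw(query)))
}

#' Find all exact occurrences of a pattern via the sparse suffix array
#'
#' For each shift s in `0..k-1`, binary-searches the pattern suffix
#' `pattern[s..]` among the sampled suffixes ([suffix_range()]); every
#' hit at sampled position q yields the candidate start `p = q - s`,
#' which is kept if `p >= 0` and the skipped s-character prefix matches
#' the text at p. Only the prefix needs verifying -- the binary search
#' already certified the rest. The union over shifts is exactly the set
#' of occurrences, each discovered by the single shift
#' `s = (k - p %% k) %% k`, so no deduplication is needed.
#'
#' Patterns shorter than k may contain no sampled position at all, so the
#' shifted-query scheme is incomplete for them; they are rejected unless
#' `scan_short = TRUE`, which falls back to a direct text scan.
#'
#' @param ssa A `sparse_suffix_array` built from `text`.
#' @param text The original text the SSA indexes.
#' @param pattern A non-empty character string, `nchar(pattern) >= ssa$k`
#'   unless `scan_short = TRUE`.
#' @param scan_short Allow patterns shorter than k via a naive scan
#'   fallback (default `FALSE`).
#' @return Sorted numeric vector of 0-based occurrence start positions.
#' @examples
#' ssa <- build_direct("banana", 2)
#' find_all(ssa, "banana", "ana")  # 1 3
#' @export
find_all <- function(ssa, text, pattern, scan_short = FALSE) {
  stopifnot(inherits(ssa, "sparse_suffix_array"),
            is.character(text), length(text) == 1L,
            is.character(pattern), length(pattern) == 1L)
  m <- nchar(pattern)
  if (m == 0L) stop("empty pattern")
  k <- ssa$k
  tb <- as.integer(charToRaw(text))
  pb <- as.integer(charToRaw(pattern))
  if (m < k) {
    if (!scan_short)
      stop(sprintf(paste0("pattern (length %d) shorter than sparseness ",
                          "factor k = %d; set scan_short = TRUE for a ",
                          "text-scan fallback"), m, k))
    return(.scan_text(tb, pb))
  }
  hits <- numeric(0)
  for (s in 0:(k - 1L)) {
    rg <- .suffix_range_raw(ssa$positions, tb, pb[(s + 1L):m])
    if (rg[2L] > rg[1L]) {
      cand <- ssa$positions[(rg[1L] + 1L):rg[2L]] - s
      cand <- cand[cand >= 0]
      if (s > 0L && length(cand)) {
        ok <- vapply(cand,
                     function(p) all(tb[(p + 1L):(p + s)] == pb[seq_len(s)]),
                     logical(1))
        cand <- cand[ok]
      }
      hits <- c(hits, cand)
    }
  }
  sort(hits)
}

# Naive overlapping scan over integer byte vectors; 0-based starts.
.scan_text <- function(tb, pb) {
  n <- length(tb)
  m <- length(pb)
  if (m > n) return(numeric(0))
  cand <- which(tb[seq_len(n - m + 1L)] == pb[1L])
  if (m > 1L) {
    for (j in 2:m) {
      if (!length(cand)) break
      cand <- cand[tb[cand + j - 1L] == pb[j]]
    }
  }
  as.numeric(cand - 1L)
}
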