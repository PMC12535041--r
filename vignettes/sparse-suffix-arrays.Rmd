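---
title: "Direct sparse suffix array construction by k-mer bit-packing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct sparse suffix array construction by k-mer bit-packing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsesa)
```

## The problem

A suffix array of a text of length $n$ lists all $n$ suffix start
positions in lexicographic order, and a binary search over it finds the
range of suffixes beginning with a query in $O(m \log n)$ time. For large
biological references -- protein databases, genomes -- the array itself
(8 bytes per entry) dwarfs the text. A *sparse suffix array* (SSA) with
sparseness factor $k$ keeps only the suffixes starting at positions
divisible by $k$: $\lceil n/k \rceil$ entries, an immediate $k$-fold
saving, at the cost of slower queries.

The catch is construction. The classical route builds the *full* suffix
array first and discards all but every $k$-th entry, so peak memory never
drops below that of full construction. This package constructs the SSA
*directly*:

1. assign each of the $\sigma$ distinct characters an integer code
   $1..\sigma$ in ascending character order, using
   $b = \lceil \log_2(\sigma+1) \rceil$ bits (code 0 is reserved, see
   below);
2. bit-pack each non-overlapping $k$-mer into one unsigned integer,
   leftmost character in the most significant bits, so that integer order
   of blocks equals lexicographic order of $k$-mers;
3. suffix-sort the packed sequence -- which has only about
   $\lceil n/k \rceil$ elements -- with induced sorting (SA-IS), and
   multiply every resulting position by $k$.

Because the packing is strictly order-preserving, comparing two packed
suffixes blockwise is the same comparison as comparing the two original
suffixes characterwise, and the result is *identical, entry for entry*,
to the subsampled SSA. The sorter's input is $k$ times shorter; what grows
instead is the transformed alphabet, $2^{bk}$ possible block values, which
drives the bucket memory of induced sorting. For the 20-letter amino-acid
alphabet ($b = 5$) and $k = 3$ a block needs 15 bits and fits a 16-bit
word:

```{r}
aa <- build_alphabet("ACDEFGHIKLMNPQRSTVWY")
p  <- pack_text(encode_text("MAGICPEPTIDES", aa), 3)
c(bits = p$bits_per_symbol * p$k, word = p$word_bits)
```

## Sentinel and tail handling

Induced sorting needs the sequence to end in a unique minimal terminator,
and the order-preservation argument needs partially filled tail blocks to
compare *smaller* than any block of real characters. Both are solved by
one convention: code 0 is never assigned to a real character. The encoder
conceptually appends one sentinel (code 0) after the text and pads with
further sentinels so that the packed sequence ends in exactly one
all-zero block -- $\lceil n/k \rceil + 1$ blocks in total. The all-zero
block is a strict minimum (every other block starts with a code
$\ge 1$ in its most significant bits), and a tail block that mixes real
characters with sentinel padding sorts exactly where characterwise
comparison of the original text would put it. Reserving a code point
costs nothing for the alphabets this method targets: $20$ amino acids
still fit 5 bits, $4$ nucleotides still fit 3.

Packed suffix positions that fall entirely inside the sentinel region
($t \cdot k \ge n$) are discarded by position-value filtering after
sorting, so the SSA contains genuine text positions only. They happen to
sort first (the sentinel region is lexicographically smallest), but the
filter does not rely on that.

## The three construction routes

`build_direct(text, k)` is the method above. `build_sampled(text, k)` is
the classical baseline -- full suffix array over the character codes plus
sentinel, sentinel entry dropped, positions filtered to multiples of
$k$ -- kept as the reference the direct route is validated against.
`build_with_divisor(text, k, d)` handles large $k$: it builds directly at
a divisor $d$ of $k$ (keeping the transformed alphabet at $2^{bd}$) and
subsamples to multiples of $k$ afterwards; the output is identical to a
direct build at $k$ whenever the latter is feasible.

```{r}
build_direct("banana", 2)$positions    # == build_sampled("banana", 2)
build_with_divisor("banana", 4, 2)$positions
```

## Searching the SSA

A pattern occurrence at position $p$ need not start at a sampled
position, so `find_all()` performs $k$ shifted queries: for each shift
$s \in 0..k-1$ it binary-searches the pattern *suffix* starting at $s$
(`suffix_range()`, characterwise against the original text); each hit at
sampled position $q$ proposes the candidate start $p = q - s$, accepted
if $p \ge 0$ and the skipped $s$-character prefix matches the text at
$p$. Only that prefix needs verification -- the binary search already
certified the rest. Each occurrence is found by exactly the one shift
$s = (k - p \bmod k) \bmod k$, so the union needs no deduplication.

Patterns shorter than $k$ can sit strictly between two sampled positions
and are invisible to every shift; they are rejected unless
`scan_short = TRUE` enables a plain text-scan fallback. This is the
memory/speed trade-off the sparseness factor embodies, made explicit at
the API boundary.

```{r}
ssa <- build_direct("banana", 2)
find_all(ssa, "banana", "ana")
```

## Memory model and choosing k

The sorting step of each route allocates, in words: the input sequence,
the suffix array, and one dense bucket-count array sized by the alphabet
upper bound. `construction_footprint()` evaluates this model, and every
builder attaches the actually allocated counts as the `words` attribute,
so model and implementation can be cross-checked:

- direct: $\lceil n/k \rceil + 1$ (input) $+\ \lceil n/k \rceil + 1$
  (SA) $+\ 2^{bk}$ (buckets);
- sampled: $(n+1) + (n+1) + (\sigma+1)$, independent of $k$.

The direct footprint falls with $k$ until the $2^{bk}$ bucket term takes
over, then rises steeply -- the characteristic U-shape that makes
moderate $k$ (and small alphabets) the sweet spot, and the divisor
strategy the escape hatch beyond it:

```{r}
f <- sapply(2:16, function(k) construction_footprint(1e7, 4, k, "direct"))
rbind(k = 2:16, Mwords = round(f / 1e6, 2))
construction_footprint(1e7, 4, 4, "sampled") / 1e6
```

## Numerical and implementation choices

- **Positions are 0-based** throughout, as is standard for suffix
  arrays; R-side containers are plain numeric vectors plus small S3
  records.
- **Symbol order is native byte order** (case-sensitive, no collation,
  no IUPAC equivalence). This is deterministic, matches standard
  suffix-array practice, and fixes the otherwise ambiguous rank of a
  FASTA separator such as `'-'` (byte 45, below all letters and digits).
- **Packed width is capped at 53 bits** ($b \cdot k \le 53$): block
  values live in R doubles, which are exact integers up to $2^{53}$.
  The cap is not a practical loss -- dense bucket arrays make direct
  construction infeasible long before that -- and the error message
  points to `build_with_divisor()`.
- **Bucket arrays are dense and sized exactly by the alphabet upper
  bound** (no sparse/hash buckets), matching the memory model above;
  `sais()` accepts bounds up to $2^{26}$. The SA-IS kernel is compiled
  (C++ via Rcpp) with 64-bit values at the top level and 32-bit names in
  recursion levels; texts are limited to $2^{31} - 1$ characters by the
  32-bit position type.
- **Storage words are the standard widths** 8/16/32/64; a 15-bit block
  reports a 16-bit word.
- **Ties cannot occur**: the terminator makes all suffixes distinct, so
  every suffix order is unique and all cross-route comparisons are exact
  `identical()` checks, not tolerance checks.
- **Degenerate inputs**: single-character texts, $k > n$, $k = 1$ (which
  must and does reproduce the full suffix array) are all legal;
  empty texts and empty patterns/queries are errors.

## What the synthetic generator does and does not emulate

`generate_synthetic()` draws i.i.d. uniform characters -- the right
fixture for correctness testing, since the equivalence of the construction
routes and the soundness of search are combinatorial identities that hold
for every text. It does *not* emulate the skewed composition,
repetitiveness, or long runs of real genomes and proteomes, which affect
*constant factors* (LMS density, recursion depth) but not correctness;
adversarial low-complexity and run-heavy inputs are covered separately in
the test suite. Wall-clock and resident-memory behaviour on real datasets
is hardware- and data-dependent and is deliberately out of scope: the
package validates the memory *model* (allocation word counts) and the
direction of its trend, not absolute timings.

The test suite validates construction equivalence on 500 random texts
(alphabet sizes 2--25, lengths up to 2,000, $k$ up to 8, jointly
constrained so the dense bucket array stays allocatable, $bk \le 24$) and
exhaustively on all 9,840 texts of length $\le 8$ over a three-letter
alphabet; sorting against a brute-force oracle on 500 random integer
sequences; search against a naive scan on 1,000 text/pattern pairs
including occurrences planted at position 0, at $n-m$, and straddling
block boundaries; and the footprint trend on a 10 Mb synthetic
nucleotide text. These sizes keep the whole suite in a few minutes while
leaving no code path untested.

## Known limitations

- No ISA/LCP construction, maximal-exact-match finding, approximate
  matching, or compressed/learned index layers.
- Alphabets are single-byte and limited to 64 distinct symbols; no
  Unicode collation.
- The index file stores positions and metadata but not the text; search
  therefore needs the original input alongside the index (the `query`
  subcommand takes both).
- Matches may span FASTA record separators; interpreting or rejecting
  them (`--reject-spanning`) is left to the caller.
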