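# sparsesa

Direct construction of sparse suffix arrays for nucleotide, protein and
other small-alphabet texts, with exact pattern search.

## What it does

A sparse suffix array (SSA) with sparseness factor *k* keeps only the
suffixes of a text starting at positions divisible by *k* —
⌈n/k⌉ entries instead of *n* — trading query speed for a *k*-fold memory
saving. The classical construction builds the **full** suffix array and
subsamples it, so peak memory never shrinks. `sparsesa` builds the SSA
directly:

1. each distinct character gets an integer code 1..σ in ascending
   character order, using b = ⌈log₂(σ+1)⌉ bits (code 0 is a reserved
   sentinel);
2. each non-overlapping k-mer is bit-packed into one unsigned integer,
   leftmost character in the most significant bits, so integer order of
   blocks equals lexicographic order of k-mers;
3. the packed sequence — only ~⌈n/k⌉ integers — is suffix-sorted with
   induced sorting (SA-IS, in compiled code), and positions are
   multiplied by k.

The result is identical, entry for entry, to the subsampled SSA, but the
sorter's input is k times shorter. The price is the transformed alphabet:
2^(b·k) bucket counters during sorting, which is why the method shines
for small alphabets and moderate k, and why `build_with_divisor()` exists
for large k (build at a divisor d of k, then subsample).

Search over the SSA uses k shifted binary searches with in-text
verification of the skipped prefix, returning exactly the occurrence set
of a naive scan for any pattern of length ≥ k.

## Worked example

```r
library(sparsesa)

ssa <- build_direct("banana", k = 2)
ssa$positions
#> [1] 0 4 2          # suffixes "banana", "na", "nana" in sorted order

identical(ssa$positions, build_sampled("banana", 2)$positions)
#> [1] TRUE           # same entries as subsampling the full suffix array

find_all(ssa, "banana", "ana")
#> [1] 1 3            # all occurrence starts (0-based)

aa <- build_alphabet("ACDEFGHIKLMNPQRSTVWY")   # 20 amino acids
p  <- pack_text(encode_text("MAGICPEPTIDES", aa), 3)
c(p$bits_per_symbol * p$k, p$word_bits)
#> [1] 15 16          # 3 x 5-bit residues per block, stored in 16-bit words
```

Positions are 0-based throughout, as is conventional for suffix arrays.

## Command line

A thin CLI wraps the same functions:

```sh
SSA_CLI=$(Rscript -e 'cat(system.file("cli", "sparsesa.R", package = "sparsesa"))')
Rscript "$SSA_CLI" build  --input proteins.fasta --sparseness 3 --output proteins.ssax
Rscript "$SSA_CLI" query  --index proteins.ssax --input proteins.fasta --pattern PEPTIDE
Rscript "$SSA_CLI" verify --input proteins.fasta --sparseness 3
Rscript "$SSA_CLI" stats  --index proteins.ssax
```

FASTA records are concatenated with a separator (default `-`); `query`
prints tab-separated `pattern  position  record-id` lines and can drop
matches spanning record boundaries (`--reject-spanning`).

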