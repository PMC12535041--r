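test_that("amino-acid text at k = 3 packs to 15-bit blocks in 16-bit words", {
  aa <- build_alphabet("ACDEFGHIKLMNPQRSTVWY")
  enc <- encode_text("MSSEQENCE" , aa)
  p <- pack_text(enc, 3)
  expect_identical(p$bits_per_symbol * p$k, 15L)
  expect_identical(p$word_bits, 16L)
  expect_true(all(p$blocks < packed_alphabet_size(aa, 3)))
})

test_that("packing matches the hand-evaluated shift-or formula", {
  acgt <- pack_text(encode_text("ACGT", build_alphabet("ACGT")), 2)
  expect_identical(acgt$blocks, c(1 * 8 + 2, 3 * 8 + 4, 0))

  ban <- pack_text(encode_text("banana", build_alphabet("banana")), 2)
  expect_identical(ban$blocks, c(2 * 4 + 1, 3 * 4 + 1, 3 * 4 + 1, 0))

  # k = 1: blocks are the codes themselves plus one terminator
  k1 <- pack_text(encode_text("banana", build_alphabet("banana")), 1)
  expect_identical(k1$blocks, c(2, 1, 3, 1, 3, 1, 0))
})

test_that("packed sequences end in a single all-zero terminator block", {
  set.seed(7)
  for (i in 1:40) {
    sigma <- sample(1:25, 1)
    n <- sample(1:60, 1)
    k <- sample(1:8, 1)
    if (bits_for_alphabet(sigma) * k > 24) next
    text <- rand_text(sigma, n)
    p <- pack_text(encode_text(text, build_alphabet(text)), k)
    m <- length(p$blocks)
    expect_identical(m, as.integer(ceiling(n / k)) + 1L)
    expect_gte(m, ceiling(n / k) + 1)
    expect_lte(m, ceiling(n / k) + 2)
    expect_identical(p$blocks[m], 0)          # unique minimal terminator
    expect_true(all(p$blocks[-m] > 0))
  }
})

test_that("transformed alphabet size is 2^(bits * k)", {
  expect_identical(packed_alphabet_size(build_alphabet("ACGT"), 2), 64)
  expect_identical(packed_alphabet_size(build_alphabet("ACDEFGHIKLMNPQRSTVWY"), 3),
                   32768)
  expect_identical(packed_alphabet_size(build_alphabet("a"), 1), 2)
})

test_that("oversized packed words are refused with a divisor hint", {
  aa <- build_alphabet("ACDEFGHIKLMNPQRSTVWY")  # 5 bits
  expect_error(packed_alphabet_size(aa, 11), "build_with_divisor")
  expect_error(pack_text(encode_text("ACDE", aa), 11), "build_with_divisor")
})

test_that("packing is injective on k-mers and preserves suffix order", {
  set.seed(11)
  for (i in 1:20) {
    sigma <- sample(2:20, 1)
    k <- sample(1:4, 1)
    if (bits_for_alphabet(sigma) * k > 24) next
    n <- sample((k + 1):300, 1)
    text <- rand_text(sigma, n)
    p <- pack_text(encode_text(text, build_alphabet(text)), k)

    # injectivity: distinct k-mers -> distinct block values
    starts <- seq(1, n - k + 1, by = k)
    kmers <- substring(text, starts, starts + k - 1)
    expect_identical(anyDuplicated(p$blocks[seq_along(starts)]) > 0,
                     anyDuplicated(kmers) > 0)

    # order preservation: comparing packed suffixes block-wise equals
    # comparing original suffixes character-wise, at sampled positions
    blk_str <- sprintf("%010.0f", p$blocks)
    packed_sufs <- vapply(seq_along(p$blocks), function(j)
      paste(blk_str[j:length(blk_str)], collapse = ""), character(1))
    sufs <- substring(text, starts)
    for (rep in 1:10) {
      ij <- sample(seq_along(starts), 2, replace = TRUE)
      expect_identical(cmp_bytes(packed_sufs[ij[1]], packed_sufs[ij[2]]),
                       cmp_bytes(sufs[ij[1]], sufs[ij[2]]))
    }
  }
})
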