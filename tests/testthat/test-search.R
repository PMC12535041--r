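test_that("suffix_range brackets the sampled suffixes with the query prefix", {
  ssa <- build_direct("banana", 2)          # positions 0, 4, 2
  expect_identical(suffix_range(ssa, "banana", "na"), c(1L, 3L))
  expect_identical(suffix_range(ssa, "banana", "banana"), c(0L, 1L))
  rg <- suffix_range(ssa, "banana", "z")    # symbol beyond the alphabet
  expect_identical(rg[1], rg[2])
  expect_error(suffix_range(ssa, "banana", ""), "empty query")
})

test_that("find_all locates every occurrence via shifted queries", {
  ssa <- build_direct("banana", 2)
  expect_identical(find_all(ssa, "banana", "ana"), c(1, 3))
  expect_identical(find_all(ssa, "banana", "qq"), numeric(0))
  expect_identical(find_all(ssa, "banana", "na"), c(2, 4))

  # k = 1: plain full-SA search, no shifts needed
  ssa1 <- build_direct("banana", 1)
  expect_identical(find_all(ssa1, "banana", "an"), c(1, 3))
})

test_that("patterns shorter than k are rejected unless scanning is enabled", {
  ssa <- build_direct("banana", 3)
  expect_error(find_all(ssa, "banana", "an"), "shorter than sparseness")
  expect_identical(find_all(ssa, "banana", "an", scan_short = TRUE), c(1, 3))
  expect_identical(find_all(ssa, "banana", "a", scan_short = TRUE), c(1, 3, 5))
})

test_that("search equals an independent scan oracle on random texts", {
  set.seed(707)
  for (i in 1:100) {
    sk <- rand_sigma_k()
    n <- pick(sk$k:600)
    text <- rand_text(sk$sigma, n)
    ssa <- build_direct(text, sk$k)
    m <- pick(sk$k:min(n, sk$k + 10))
    pat <- if (i %% 3 == 0) rand_text(sk$sigma, m)  # often absent
           else substr(text, (p0 <- pick(0:(n - m))) + 1, p0 + m)
    expect_identical(find_all(ssa, text, pat), oracle_scan(text, pat))
  }
})

test_that("each occurrence is discovered by exactly one shift", {
  set.seed(808)
  for (i in 1:20) {
    sigma <- sample(2:6, 1)
    k <- sample(2:5, 1)
    n <- sample((k + 4):300, 1)
    text <- rand_text(sigma, n)
    ssa <- build_direct(text, k)
    m <- pick(k:min(n, k + 6))
    p0 <- pick(0:(n - m))
    pat <- substr(text, p0 + 1, p0 + m)
    # count raw per-shift discoveries; must equal the occurrence count
    tb <- as.integer(charToRaw(text)); pb <- as.integer(charToRaw(pat))
    total <- 0L
    for (s in 0:(k - 1)) {
      rg <- sparsesa:::.suffix_range_raw(ssa$positions, tb, pb[(s + 1):m])
      if (rg[2] > rg[1]) {
        cand <- ssa$positions[(rg[1] + 1):rg[2]] - s
        cand <- cand[cand >= 0]
        if (s > 0 && length(cand))
          cand <- cand[vapply(cand, function(p)
            all(tb[(p + 1):(p + s)] == pb[seq_len(s)]), logical(1))]
        total <- total + length(cand)
      }
    }
    occ <- oracle_scan(text, pat)
    expect_identical(total, length(occ))
    expect_identical(find_all(ssa, text, pat), occ)
  }
})

test_that("matches at the text ends and across block boundaries are found", {
  set.seed(909)
  for (k in 2:5) {
    n <- 120
    base <- rand_text(3, n)
    pat <- rand_text(3, k + 2)
    # plant at position 0, straddling a block boundary, and at n - m
    text <- paste0(pat, substr(base, nchar(pat) + 1, n - nchar(pat) - k - 1),
                   pat, substr(base, n - nchar(pat) - 1, n - nchar(pat)), pat)
    ssa <- build_direct(text, k)
    expect_identical(find_all(ssa, text, pat), oracle_scan(text, pat))
    expect_true(0 %in% find_all(ssa, text, pat))
    expect_true((nchar(text) - nchar(pat)) %in% find_all(ssa, text, pat))
  }
})
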