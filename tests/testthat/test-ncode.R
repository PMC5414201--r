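test_that("choose_n picks the largest dividing block length", {
  cases <- list(
    list(W = 30, N = 5L), list(W = 12, N = 4L), list(W = 9, N = 3L),
    list(W = 10, N = 5L), list(W = 8, N = 4L), list(W = 6, N = 3L),
    list(W = 20, N = 5L), list(W = 60, N = 5L), list(W = 100, N = 5L)
  )
  for (cs in cases) {
    expect_identical(choose_n(cs$W), cs$N, info = paste("W =", cs$W))
  }
})

test_that("choose_n rejects invalid window lengths, naming nearby valid ones", {
  expect_error(choose_n(7), "nearest valid")
  expect_error(choose_n(11), "nearest valid")
  expect_error(choose_n(22), "21 and 24")
  # 5 is divisible by 5 but has a single block; 4 and 3 likewise too short
  expect_error(choose_n(5))
  expect_error(choose_n(3))
  expect_error(choose_n(-2), "positive integer")
})

test_that("encoding is the lexicographic rank and decoding inverts it", {
  sc4 <- cached_scheme(3, dna4)
  expect_identical(encode_ngram("AAA", sc4), 0L)
  expect_identical(encode_ngram("AAG", sc4), 2L)
  expect_identical(encode_ngram("TTT", sc4), 63L)
  expect_identical(decode_ngram(c(0L, 63L), sc4), c("AAA", "TTT"))

  sc5 <- cached_scheme(5)
  expect_identical(encode_ngram("TTTTT", sc5), 3124L)
  expect_identical(decode_ngram(3124L, sc5), "TTTTT")

  # round trip over the full domain, both alphabets, N = 3
  for (sc in list(cached_scheme(3, dna4), cached_scheme(3))) {
    codes <- 0:(sc$sigma^sc$N - 1L)
    expect_identical(encode_ngram(decode_ngram(codes, sc), sc), codes)
  }

  # encoded words are in lexicographic ascending order
  sc <- cached_scheme(3, dna4)
  words <- decode_ngram(0:63, sc)
  expect_identical(words, sort(words, method = "radix"))
})

test_that("encoding rejects out-of-alphabet letters and out-of-range codes", {
  sc4 <- cached_scheme(3, dna4)
  expect_error(encode_ngram("ANA", sc4), "outside the alphabet")
  expect_error(encode_ngram("AA", sc4), "exactly N")
  expect_error(decode_ngram(64L, sc4), "codes must be")
  expect_error(decode_ngram(-1L, sc4), "codes must be")
})

test_that("mismatch matrix satisfies metric and shell-count invariants", {
  for (alpha in list(dna4, c("A", "C", "G", "N", "T"))) {
    sc <- cached_scheme(3, alpha)
    M <- cached_matrix(3, alpha)
    S <- as.integer(sc$sigma^sc$N)
    expect_identical(dim(M), c(S, S)) # sigma^(2N) entries
    expect_identical(unname(diag(M)), rep(0L, S))
    expect_true(all(M == t(M)))
    expect_true(all(M <= sc$N))

    # triangle inequality via one min-plus pass: M <= min_h (M[,h] + M[h,])
    minplus <- matrix(Inf, S, S)
    for (h in seq_len(S)) {
      minplus <- pmin(minplus, outer(M[, h], M[h, ], "+"))
    }
    expect_true(all(M <= minplus))

    # every row has exactly choose(N,d)*(sigma-1)^d codes at distance d
    expected <- choose(sc$N, 0:sc$N) * (sc$sigma - 1)^(0:sc$N)
    for (i in c(1L, 2L, S %/% 2L, S)) {
      counts <- tabulate(M[i, ] + 1L, nbins = sc$N + 1L)
      expect_identical(counts, as.integer(expected))
    }
    # and in aggregate across all rows
    total <- tabulate(M + 1L, nbins = sc$N + 1L)
    expect_identical(total, as.integer(S * expected))
  }
})

test_that("matrix entries equal letter-level Hamming distances of decoded words", {
  sc <- cached_scheme(3, dna4)
  M <- cached_matrix(3, dna4)
  words <- decode_ngram(0:63, sc)
  set.seed(42)
  idx <- cbind(sample(64, 300, replace = TRUE), sample(64, 300, replace = TRUE))
  for (r in seq_len(nrow(idx))) {
    expect_identical(
      M[idx[r, 1], idx[r, 2]],
      as.integer(letter_hamming(words[idx[r, 1]], words[idx[r, 2]]))
    )
  }
})

test_that("hamming_capped equals the naive string Hamming below the cap", {
  sc <- cached_scheme(5)
  M <- cached_matrix(5)
  W <- 20L
  set.seed(7)
  for (rep in 1:200) {
    a <- random_word(W, sc$alphabet)
    b <- random_word(W, sc$alphabet)
    va <- encode_ngram(substring(a, c(1, 6, 11, 16), c(5, 10, 15, 20)), sc)
    vb <- encode_ngram(substring(b, c(1, 6, 11, 16), c(5, 10, 15, 20)), sc)
    expect_identical(
      hamming_capped(va, vb, W, M),
      as.integer(letter_hamming(a, b))
    )
  }
})

test_that("hamming_capped early-terminates to cap + 1", {
  sc <- cached_scheme(3, dna4)
  M <- cached_matrix(3, dna4)
  a <- encode_ngram(c("AAA", "AAA"), sc)
  b <- encode_ngram(c("CCC", "GGG"), sc) # distance 6
  expect_identical(hamming_capped(a, b, 2L, M), 3L)
  expect_identical(hamming_capped(a, a, 0L, M), 0L)
  expect_identical(hamming_capped(a, b, 6L, M), 6L)
  expect_error(hamming_capped(a, b[1], 2L, M), "equal length")
})

test_that("distance shells partition the neighborhood with exact sizes", {
  M4 <- cached_matrix(3, dna4)
  shells <- neighbors_by_distance(17L, 3L, M4)
  expect_identical(lengths(shells), c(1L, 9L, 27L, 27L))
  expect_identical(shells[[1]], 17L)
  expect_identical(sort(unlist(shells)), 0:63) # max_d = N covers everything
  # buckets are disjoint and consistent with the matrix
  row <- M4[18L, ]
  for (d in 0:3) {
    expect_identical(shells[[d + 1]], which(row == d) - 1L)
  }

  M5 <- cached_matrix(5)
  sh <- neighbors_by_distance(0L, 2L, M5)
  expect_identical(lengths(sh), c(1L, 20L, 160L)) # choose(5,d)*4^d

  expect_identical(neighbors_by_distance(5L, 0L, M4), list(5L))
})
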