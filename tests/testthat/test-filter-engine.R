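test_that("scan parameters validate W, k, and mode", {
  p <- scan_parameters(30, 2)
  expect_identical(p$N, 5L)
  expect_identical(p$mode, "d")
  expect_error(scan_parameters(7, 0), "nearest valid")
  expect_error(scan_parameters(12, -1), "non-negative")
  expect_error(scan_parameters(12, 0, mode = "x"))
  expect_warning(scan_parameters(12, 6), "tenfold")
})

test_that("exists_within_k finds matches and honors self-exclusion", {
  sc <- cached_scheme(3)
  M <- cached_matrix(3)
  x <- encode_ngram(c("ACG", "TTA"), sc)
  tree <- build_dictree(matrix(x, nrow = 1), sc, 6L)

  expect_true(exists_within_k(tree, x, 0L, M))
  # sole exact occurrence discounted -> no other vector within k
  expect_false(exists_within_k(tree, x, 0L, M, exclude_one_exact_self = TRUE))
  tree2 <- insert_vector(tree, x)
  expect_true(exists_within_k(tree2, x, 0L, M, exclude_one_exact_self = TRUE))

  empty <- build_dictree(matrix(integer(), 0, 2), sc, 6L)
  expect_false(exists_within_k(empty, x, 3L, M))
})

test_that("one substitution separates at k = 0 but not k = 1", {
  # taboo: all 12-mers of a 15-mer; query word differs by one letter from
  # one of them (checked against the letter-level oracle)
  sc <- cached_scheme(4)
  M <- cached_matrix(4)
  taboo <- make_record("b", "ACGTACGTACGTACG")
  query <- make_record("q", "ACGTACGTACGA")
  tree <- build_dictree(fragment_taboo(taboo, 12L, sc), sc, 12L)
  x <- encode_ngram(substring(query$sequence, c(1, 5, 9), c(4, 8, 12)), sc)

  expect_false(exists_within_k(tree, x, 0L, M))
  expect_true(exists_within_k(tree, x, 1L, M))
  oracle <- brute_force_kdisjoint(query, taboo, 12L, 0L)
  expect_identical(oracle$label, "disjoint")
  oracle1 <- brute_force_kdisjoint(query, taboo, 12L, 1L)
  expect_identical(oracle1$label, "intersection")
})

test_that("classify_window labels the partition of windows", {
  sc <- cached_scheme(3)
  M <- cached_matrix(3)
  rec <- generate_genome(60, seed = 4, record_id = "r")
  params <- scan_parameters(12, 0)
  # taboo contains the query verbatim -> every window intersecting
  tree <- build_dictree(fragment_taboo(rec, 12L, sc), sc, 12L)
  win <- extract_windows(rec, 12L, scheme = sc)
  labels <- vapply(seq_len(nrow(win)), function(r) {
    classify_window(win[r, ], tree, params, M)$label
  }, character(1))
  expect_true(all(labels == "intersection"))
  # empty taboo -> every window disjoint
  empty <- build_dictree(matrix(integer(), 0, 4), sc, 12L)
  labels <- vapply(seq_len(nrow(win)), function(r) {
    classify_window(win[r, ], tree = empty, params, M)$label
  }, character(1))
  expect_true(all(labels == "disjoint"))
})

test_that("compiled scan agrees with the pure-R search path", {
  sc <- cached_scheme(3)
  M <- cached_matrix(3)
  query <- generate_genome(150, seed = 31, record_id = "q")
  taboo <- generate_genome(400, seed = 32, record_id = "t")
  tree <- build_dictree(fragment_taboo(taboo, 9L, sc), sc, 9L)
  win <- extract_windows(query, 9L, scheme = sc)
  for (k in 0:2) {
    params <- scan_parameters(9, k)
    bulk <- scan_records(query, tree, params, M)
    single <- vapply(seq_len(nrow(win)), function(r) {
      exists_within_k(tree, win$vector[[r]], k, M)
    }, logical(1))
    expect_identical(bulk$label == "intersection", single)
  }
})

test_that("workload partitions are contiguous, covering, and balanced", {
  p <- partition_workload(10L, 3L)
  expect_identical(p$end - p$start + 1L, c(4L, 3L, 3L))
  expect_identical(p$start[1], 1L)
  expect_identical(p$end[3], 10L)
  expect_identical(nrow(partition_workload(0L, 4L)), 0L)
  p1 <- partition_workload(5L, 8L) # more threads than windows
  expect_identical(sum(p1$end - p1$start + 1L), 5L)
  expect_true(all(p1$start <= p1$end))
  for (n in c(1L, 7L, 100L)) {
    for (t in c(1L, 2L, 4L)) {
      p <- partition_workload(n, t)
      covered <- unlist(Map(seq, p$start, p$end))
      expect_identical(covered, seq_len(n))
      expect_lte(diff(range(p$end - p$start + 1L)), 1L)
    }
  }
})

test_that("output is identical for any thread count", {
  query <- generate_genome(300, seed = 41, record_id = "q")
  taboo <- generate_genome(1200, seed = 42, record_id = "t")
  ref <- engine_calls(query, taboo, 12L, 1L, threads = 1L)
  for (t in c(2L, 4L)) {
    expect_identical(engine_calls(query, taboo, 12L, 1L, threads = t), ref)
  }
})

test_that("disjoint and intersection sets partition the windows", {
  query <- generate_genome(250, seed = 51, record_id = "q")
  taboo <- generate_genome(900, seed = 52, record_id = "t")
  calls <- engine_calls(query, taboo, 15L, 1L)
  expect_identical(nrow(calls), 250L - 15L + 1L)
  expect_true(all(calls$label %in% c("disjoint", "intersection")))
  expect_identical(
    sum(calls$label == "disjoint") + sum(calls$label == "intersection"),
    nrow(calls)
  )
})

test_that("raising k only shrinks the disjoint set", {
  query <- generate_genome(400, seed = 61, record_id = "q")
  taboo <- generate_genome(1500, seed = 62, record_id = "t")
  prev <- NULL
  for (k in 0:3) {
    disj <- dplyr::filter(engine_calls(query, taboo, 12L, k), label == "disjoint")$position
    if (!is.null(prev)) expect_true(all(disj %in% prev))
    prev <- disj
  }
})

test_that("a window whose reverse complement is in the taboo set intersects", {
  word <- "ACGGTCAATCGG" # 12-mer, not an rc-palindrome
  taboo <- make_record("t", paste0("TTTTT", reverse_complement(word), "AAAAA"))
  query <- make_record("q", word)
  calls <- engine_calls(query, taboo, 12L, 0L)
  expect_identical(calls$label, "intersection")
  # the letter-level oracle agrees
  oracle <- brute_force_kdisjoint(query, taboo, 12L, 0L)
  expect_identical(oracle$label, "intersection")
})
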