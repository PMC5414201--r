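# Shared, lazily-built schemes and mismatch matrices. The N = 5 five-letter
# table has 5^10 entries, so each (N, alphabet) pair is built once per run.
.cache <- new.env(parent = emptyenv())

cached_scheme <- function(N, alphabet = c("A", "C", "G", "N", "T")) {
  key <- paste0("scheme_", N, "_", paste(alphabet, collapse = ""))
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- encoding_scheme(N, alphabet)
  }
  .cache[[key]]
}

cached_matrix <- function(N, alphabet = c("A", "C", "G", "N", "T")) {
  key <- paste0("matrix_", N, "_", paste(alphabet, collapse = ""))
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- mismatch_matrix(cached_scheme(N, alphabet))
  }
  .cache[[key]]
}

dna4 <- c("A", "C", "G", "T")

make_record <- function(id, sequence, source_file = NA_character_) {
  tibble::tibble(
    source_file = source_file, record_id = id, sequence = sequence
  )
}

# letter-level Hamming distance, the plain-R oracle for encoded comparisons
letter_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

random_word <- function(n, letters = dna4) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# engine run on in-memory records, bypassing directory I/O
engine_calls <- function(query, taboo, W, k, self_exclude = FALSE,
                         threads = 1L) {
  N <- choose_n(W)
  scheme <- cached_scheme(N)
  M <- cached_matrix(N)
  tree <- build_dictree(fragment_taboo(taboo, W, scheme), scheme, W)
  params <- scan_parameters(W, k,
    self_exclude = self_exclude, threads = threads
  )
  scan_records(query, tree, params, M)
}
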