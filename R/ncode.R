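#' Encoding scheme for fixed-length DNA words
#'
#' N-coding maps every length-`N` word over an ordered alphabet to its
#' lexicographic rank, a unique integer in `[0, sigma^N - 1]`. A length-`W`
#' window then becomes a vector of `W/N` such codes, and Hamming distances
#' between windows reduce to `W/N` lookups in a precomputed block-distance
#' table (see [mismatch_matrix()]).
#'
#' The working alphabet is the five-letter DNA alphabet A, C, G, N, T (the
#' canonical unknown base N is an ordinary letter: N-vs-N contributes zero
#' mismatches). A four-letter A, C, G, T scheme can be constructed for
#' N-free inputs and for the classic worked examples (`"AAA"` -> 0,
#' `"AAG"` -> 2, `"TTT"` -> 63 at `N = 3`).
#'
#' @param N block length for encoding; one of 3, 4 or 5. Capped at 5 because
#'   the mismatch matrix grows as `sigma^(2N)`.
#' @param alphabet ordered character vector of unique single letters, sorted
#'   ascending. Default `c("A","C","G","N","T")`.
#' @return An object of class `encoding_scheme`: a list with elements
#'   `alphabet`, `sigma` and `N`.
#' @examples
#' sc4 <- encoding_scheme(3, c("A", "C", "G", "T"))
#' encode_ngram("AAG", sc4) # 2
#' decode_ngram(63, sc4)    # "TTT"
#' @export
encoding_scheme <- function(N = 5L, alphabet = c("A", "C", "G", "N", "T")) {
  if (!is.numeric(N) || length(N) != 1L || !(N %in% c(3L, 4L, 5L))) {
    abort("`N` must be 3, 4 or 5.")
  }
  alphabet <- as.character(alphabet)
  if (anyDuplicated(alphabet) || any(nchar(alphabet) != 1L)) {
    abort("`alphabet` must be unique single letters.")
  }
  if (is.unsorted(alphabet, strictly = TRUE)) {
    abort("`alphabet` must be sorted lexicographically ascending.")
  }
  structure(
    list(alphabet = alphabet, sigma = length(alphabet), N = as.integer(N)),
    class = "encoding_scheme"
  )
}

#' @export
print.encoding_scheme <- function(x, ...) {
  cat(sprintf(
    "<encoding_scheme> alphabet {%s} (sigma = %d), N = %d, codes 0..%d\n",
    paste(x$alphabet, collapse = ","), x$sigma, x$N, x$sigma^x$N - 1L
  ))
  invisible(x)
}

#' Choose the encoding block length N for a window length W
#'
#' `N` must divide `W` and lie in \{3, 4, 5\}; when several values qualify the
#' largest is taken (a larger block means fewer table lookups per window).
#' The two-level sub-list addressing additionally needs at least two blocks
#' per window, i.e. `W/N >= 2`.
#'
#' @param W window length (positive integer, at least 6).
#' @return The chosen block length (integer 3, 4 or 5).
#' @examples
#' choose_n(30) # 5
#' choose_n(12) # 4
#' choose_n(9)  # 3
#' @export
choose_n <- function(W) {
  if (!is.numeric(W) || length(W) != 1L || W != as.integer(W) || W < 1L) {
    abort("`W` must be a single positive integer.")
  }
  W <- as.integer(W)
  divs <- c(5L, 4L, 3L)[W %% c(5L, 4L, 3L) == 0L]
  ok <- divs[W %/% divs >= 2L]
  if (length(ok) == 0L) {
    near <- nearest_valid_w(W)
    abort(sprintf(
      "W = %d is not a multiple of 3, 4 or 5 with at least two blocks; nearest valid values are %s.",
      W, paste(near, collapse = " and ")
    ))
  }
  ok[[1L]]
}

# nearest window lengths accepted by choose_n(), below and above W
nearest_valid_w <- function(W) {
  valid <- function(w) {
    w >= 6L && any(w %% c(3L, 4L, 5L) == 0L & w %/% c(3L, 4L, 5L) >= 2L)
  }
  lo <- W - 1L
  while (lo >= 6L && !valid(lo)) lo <- lo - 1L
  hi <- W + 1L
  while (!valid(hi)) hi <- hi + 1L
  if (lo >= 6L) c(lo, hi) else hi
}

#' Encode / decode fixed-length words as integer codes
#'
#' `encode_ngram()` returns the lexicographic rank of each word under the
#' scheme's alphabet order (the positional base-`sigma` value of its letters);
#' `decode_ngram()` is the exact inverse. Both are vectorized.
#'
#' @param word character vector of words, each of length `scheme$N`, over the
#'   scheme alphabet.
#' @param code integer vector of codes in `[0, sigma^N - 1]`.
#' @param scheme an [encoding_scheme()].
#' @return For `encode_ngram()` an integer vector of codes; for
#'   `decode_ngram()` a character vector of words.
#' @examples
#' sc <- encoding_scheme(3, c("A", "C", "G", "T"))
#' encode_ngram(c("AAA", "AAG", "TTT"), sc) # 0 2 63
#' decode_ngram(0:3, sc)
#' @export
encode_ngram <- function(word, scheme) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  if (any(nchar(word) != scheme$N)) {
    abort(sprintf("every word must have exactly N = %d letters.", scheme$N))
  }
  chars <- strsplit(word, "", fixed = TRUE)
  pow <- scheme$sigma^((scheme$N - 1L):0L)
  out <- vapply(chars, function(ch) {
    d <- match(ch, scheme$alphabet) - 1L
    if (anyNA(d)) {
      abort(sprintf(
        "letter(s) outside the alphabet {%s}; sanitize sequences first.",
        paste(scheme$alphabet, collapse = ",")
      ))
    }
    sum(d * pow)
  }, numeric(1))
  as.integer(out)
}

#' @rdname encode_ngram
#' @export
decode_ngram <- function(code, scheme) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  max_code <- scheme$sigma^scheme$N - 1
  if (any(code < 0 | code > max_code | code != floor(code))) {
    abort(sprintf("codes must be integers in [0, %d].", max_code))
  }
  pow <- scheme$sigma^((scheme$N - 1L):0L)
  vapply(code, function(cd) {
    d <- (cd %/% pow) %% scheme$sigma
    paste(scheme$alphabet[d + 1L], collapse = "")
  }, character(1))
}

#' Precomputed block-level Hamming distance table
#'
#' Builds the `sigma^N` x `sigma^N` table whose entry for codes `(i, j)` is
#' the Hamming distance between the words they decode to. With it, the
#' distance between two W-letter windows is the sum of `W/N` table lookups.
#' The table is dense; `N = 5` over the five-letter alphabet gives
#' `5^10` (about 9.8 million) entries, which is why `N` is capped at 5.
#'
#' @param scheme an [encoding_scheme()].
#' @return An integer matrix of class `mismatch_matrix` with a `scheme`
#'   attribute. Row/column for code `c` is index `c + 1`.
#' @examples
#' M <- mismatch_matrix(encoding_scheme(3, c("A", "C", "G", "T")))
#' M[0 + 1, 2 + 1]  # distance AAA vs AAG: 1
#' M[0 + 1, 63 + 1] # distance AAA vs TTT: 3
#' @export
mismatch_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  S <- scheme$sigma^scheme$N
  codes <- 0:(S - 1L)
  pow <- scheme$sigma^((scheme$N - 1L):0L)
  M <- matrix(0L, S, S)
  for (p in seq_len(scheme$N)) {
    d <- (codes %/% pow[p]) %% scheme$sigma
    M <- M + outer(d, d, "!=")
  }
  storage.mode(M) <- "integer"
  structure(M, scheme = scheme, class = c("mismatch_matrix", class(M)))
}

#' @export
print.mismatch_matrix <- function(x, ...) {
  sc <- attr(x, "scheme")
  cat(sprintf(
    "<mismatch_matrix> %d x %d block distances (sigma = %d, N = %d)\n",
    nrow(x), ncol(x), sc$sigma, sc$N
  ))
  invisible(x)
}

#' Hamming distance between encoded windows, capped at a threshold
#'
#' Sums block distances from the mismatch matrix element-wise, stopping as
#' soon as the running total exceeds `cap`; callers only ever test
#' `distance <= k`, so on early exit `cap + 1` is returned rather than the
#' exact overshoot.
#'
#' @param a,b integer code vectors of equal length (0-based codes).
#' @param cap non-negative integer threshold.
#' @param matrix a [mismatch_matrix()] built from the same scheme.
#' @return The true distance if it is `<= cap`, otherwise `cap + 1`.
#' @export
hamming_capped <- function(a, b, cap, matrix) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must have equal length.")
  }
  stopifnot(cap >= 0)
  d <- 0L
  for (l in seq_along(a)) {
    d <- d + matrix[a[[l]] + 1L, b[[l]] + 1L]
    if (d > cap) return(as.integer(cap + 1L))
  }
  d
}

#' Codes grouped by block distance from a focal code
#'
#' Enumerates, for each distance `d` in `0..max_d`, every code whose decoded
#' word is exactly `d` mismatches from the focal code's word. These distance
#' shells drive the candidate sub-list enumeration: shell `d` has
#' `choose(N, d) * (sigma - 1)^d` members.
#'
#' @param code focal code (0-based).
#' @param max_d largest distance of interest, `0 <= max_d <= N`.
#' @param matrix a [mismatch_matrix()].
#' @return A list of length `max_d + 1`; element `d + 1` is the integer
#'   vector of codes at distance exactly `d`.
#' @export
neighbors_by_distance <- function(code, max_d, matrix) {
  sc <- attr(matrix, "scheme")
  stopifnot(max_d >= 0, max_d <= sc$N)
  row <- matrix[code + 1L, ]
  lapply(0:max_d, function(d) which(row == d) - 1L)
}
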