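#' Two-level address-partitioned index over encoded taboo windows
#'
#' Stored window vectors are partitioned into sub-lists addressed by their
#' first two block codes: a vector `<62, 3, ...>` lives in the sub-list at
#' address `(62, 3)`. A query then only needs to visit the sub-lists whose
#' address-level distance can still permit a within-k match (see
#' [candidate_addresses()]). Exact-occurrence multiplicities are tracked so
#' that self-comparison runs (query set == taboo set) can discount one exact
#' occurrence of each window (see [exists_within_k()]).
#'
#' Empty sub-lists are never materialized; addressing is sparse.
#'
#' @param vectors integer matrix of encoded windows (one per row, 0-based
#'   codes, at least two columns), e.g. from [fragment_taboo()]; a list of
#'   equal-length integer vectors is also accepted.
#' @param scheme the [encoding_scheme()] the vectors were encoded with.
#' @param W the window length the vectors represent.
#' @return An object of class `dictree`.
#' @export
build_dictree <- function(vectors, scheme, W) {
  if (is.list(vectors)) {
    vectors <- do.call(rbind, lapply(vectors, as.integer))
  }
  if (is.null(vectors) || nrow(vectors) == 0L) {
    Lv <- max(2L, W %/% scheme$N)
    vectors <- matrix(integer(), 0L, Lv)
  }
  if (ncol(vectors) < 2L) {
    abort("window vectors need at least two blocks for two-level addressing.")
  }
  storage.mode(vectors) <- "integer"
  S <- scheme$sigma^scheme$N
  key <- as.double(vectors[, 1L]) * S + vectors[, 2L]
  ord <- order(key)
  sorted <- vectors[ord, , drop = FALSE]
  skey <- key[ord]
  ukeys <- unique(skey)
  # CSR-style offsets: rows starts[a]..starts[a+1]-1 of `sorted` share ukeys[a]
  starts <- c(0L, cumsum(tabulate(match(skey, ukeys), length(ukeys))))
  vec_id <- do.call(paste, c(as.data.frame(vectors), sep = "-"))
  mult <- table(vec_id)
  structure(
    list(
      sorted = sorted,
      ukeys = ukeys,
      starts = as.integer(starts),
      multiplicities = stats::setNames(as.integer(mult), names(mult)),
      scheme = scheme,
      W = as.integer(W),
      vector_length = ncol(vectors),
      n = nrow(vectors)
    ),
    class = "dictree"
  )
}

#' @export
print.dictree <- function(x, ...) {
  cat(sprintf(
    "<dictree> %d stored vectors of length %d in %d sub-lists (W = %d, N = %d)\n",
    x$n, x$vector_length, length(x$ukeys), x$W, x$scheme$N
  ))
  invisible(x)
}

#' Insert a single encoded window vector
#'
#' Appends `v` to the sub-list addressed by its first two codes and bumps its
#' exact-occurrence multiplicity. Intended for small incremental use; bulk
#' construction goes through [build_dictree()].
#'
#' @param tree a `dictree`.
#' @param v integer code vector of length `tree$vector_length`.
#' @return The updated `dictree`.
#' @export
insert_vector <- function(tree, v) {
  stopifnot(inherits(tree, "dictree"))
  if (length(v) != tree$vector_length) {
    abort(sprintf(
      "vector length %d does not match the tree's %d.",
      length(v), tree$vector_length
    ))
  }
  all_vecs <- rbind(tree$sorted, as.integer(v))
  build_dictree(all_vecs, tree$scheme, tree$W)
}

#' Sub-list stored at an address pair
#'
#' @param tree a `dictree`.
#' @param address length-2 integer vector `(i, j)` of 0-based codes.
#' @return Integer matrix of the vectors stored there (0 rows if none).
#' @export
sublist_at <- function(tree, address) {
  stopifnot(inherits(tree, "dictree"), length(address) == 2L)
  S <- tree$scheme$sigma^tree$scheme$N
  key <- as.double(address[[1L]]) * S + address[[2L]]
  a <- match(key, tree$ukeys)
  if (is.na(a)) {
    return(tree$sorted[0L, , drop = FALSE])
  }
  rows <- (tree$starts[a] + 1L):tree$starts[a + 1L]
  tree$sorted[rows, , drop = FALSE]
}

#' Exact-occurrence multiplicity of a vector in the index
#'
#' Counts how many times `v` was inserted (forward and reverse-complement
#' windows both count). The self-comparison protocol relies on this: a query
#' window whose only exact occurrence in the taboo set is itself has
#' multiplicity 1.
#'
#' @param tree a `dictree`.
#' @param v integer code vector.
#' @return Non-negative integer count.
#' @export
multiplicity_of <- function(tree, v) {
  stopifnot(inherits(tree, "dictree"))
  key <- paste(as.integer(v), collapse = "-")
  m <- unname(tree$multiplicities[key])
  if (is.na(m)) 0L else m
}

#' Sub-list addresses that can contain a within-k match
#'
#' For a query vector `x = <x1, x2, ...>`, a stored vector within Hamming
#' distance `k` must sit at an address `(i, j)` with
#' `M(x1, i) + M(x2, j) <= k`: the first two blocks alone already contribute
#' that much distance. `candidate_addresses()` enumerates exactly this set
#' via the precomputed distance shells of `x1` and `x2`. For `k = 0` it is
#' the singleton `(x1, x2)`.
#'
#' @param x integer code vector (only the first two elements are used).
#' @param k mismatch threshold.
#' @param matrix a [mismatch_matrix()].
#' @return A tibble with columns `i`, `j` (0-based codes) and
#'   `prefix_distance` = `M(x1,i) + M(x2,j)`, sorted by `prefix_distance`.
#' @export
candidate_addresses <- function(x, k, matrix) {
  stopifnot(length(x) >= 2L, k >= 0)
  sc <- attr(matrix, "scheme")
  kk <- min(k, 2L * sc$N) # block prefix can contribute at most 2N
  row1 <- matrix[x[[1L]] + 1L, ]
  row2 <- matrix[x[[2L]] + 1L, ]
  i_ok <- which(row1 <= kk) - 1L
  d1 <- row1[i_ok + 1L]
  j_lists <- lapply(d1, function(dd) which(row2 <= kk - dd) - 1L)
  nj <- lengths(j_lists)
  j <- unlist(j_lists, use.names = FALSE)
  if (is.null(j)) j <- integer(0)
  out <- tibble(
    i = rep(i_ok, nj),
    j = j,
    prefix_distance = rep(d1, nj) + row2[j + 1L]
  )
  dplyr::arrange(out, .data$prefix_distance, .data$i, .data$j)
}
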