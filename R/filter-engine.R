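#' Scan parameters
#'
#' Bundles the window length `W` (validated via [choose_n()]), mismatch
#' threshold `k`, output mode, self-exclusion flag and thread count.
#' `k` above 5 is permitted with a warning: the search cost grows roughly
#' tenfold per additional mismatch, so large `k` is rarely practical.
#'
#' @param W window length; must be a multiple of 3, 4 or 5 with at least two
#'   encoding blocks.
#' @param k mismatch threshold (0-5 recommended).
#' @param mode `'d'` report k-disjoint windows, `'i'` k-intersection,
#'   `'a'` both.
#' @param self_exclude discount one exact occurrence of each query window in
#'   the taboo index (for uniqueness-within-genome runs where the same
#'   sequences sit in both sets).
#' @param threads number of worker processes for the scan.
#' @return A list of class `scan_parameters`, including the chosen block
#'   length `N`.
#' @export
scan_parameters <- function(W, k, mode = c("d", "i", "a"),
                            self_exclude = FALSE, threads = 1L) {
  mode <- match.arg(mode)
  N <- choose_n(W)
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != as.integer(k)) {
    abort("`k` must be a single non-negative integer.")
  }
  if (k > 5) {
    warn(sprintf(
      "k = %d: search cost grows roughly tenfold per extra mismatch; k <= 5 is recommended.",
      as.integer(k)
    ))
  }
  stopifnot(threads >= 1L)
  structure(
    list(
      W = as.integer(W), k = as.integer(k), N = N, mode = mode,
      self_exclude = isTRUE(self_exclude), threads = as.integer(threads)
    ),
    class = "scan_parameters"
  )
}

#' @export
print.scan_parameters <- function(x, ...) {
  cat(sprintf(
    "<scan_parameters> W = %d (N = %d), k = %d, mode '%s', self_exclude %s, threads %d\n",
    x$W, x$N, x$k, x$mode, x$self_exclude, x$threads
  ))
  invisible(x)
}

#' Is any stored vector within k mismatches of a query vector?
#'
#' Reference (pure R) search path: enumerate [candidate_addresses()], walk
#' each existing sub-list, and compare with [hamming_capped()] so every
#' comparison early-terminates past `k`. With `exclude_one_exact_self`, one
#' exact occurrence of `x` itself is discounted, so the result is `TRUE` iff
#' `multiplicity_of(tree, x) >= 2` or some distinct vector lies within `k`.
#'
#' The bulk scanner ([scan_records()]) runs the same search in compiled code;
#' the test suite asserts the two paths agree.
#'
#' @param tree a [build_dictree()] index.
#' @param x integer code vector of length `tree$vector_length`.
#' @param k mismatch threshold.
#' @param matrix a [mismatch_matrix()].
#' @param exclude_one_exact_self discount one exact self occurrence.
#' @return TRUE/FALSE.
#' @export
exists_within_k <- function(tree, x, k, matrix,
                            exclude_one_exact_self = FALSE) {
  stopifnot(inherits(tree, "dictree"))
  if (length(x) != tree$vector_length) {
    abort("query vector length does not match the tree.")
  }
  if (tree$n == 0L) {
    return(FALSE)
  }
  cand <- candidate_addresses(x, k, matrix)
  n_exact <- 0L
  for (a in seq_len(nrow(cand))) {
    sub <- sublist_at(tree, c(cand$i[[a]], cand$j[[a]]))
    if (nrow(sub) == 0L) next
    for (t in seq_len(nrow(sub))) {
      d <- hamming_capped(x, sub[t, ], k, matrix)
      if (d > k) next
      if (d == 0L) {
        n_exact <- n_exact + 1L
        if (!exclude_one_exact_self || n_exact >= 2L) return(TRUE)
      } else {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Classify one query window as k-disjoint or k-intersecting
#'
#' A window is `'disjoint'` iff no taboo window (either strand) lies within
#' `k` mismatches of it; otherwise `'intersection'`.
#'
#' @param window a one-row tibble from [extract_windows()] with a `vector`
#'   column (i.e. extracted with a scheme).
#' @param tree a `dictree` built with the same scheme and `W`.
#' @param params a [scan_parameters()] object.
#' @param matrix a [mismatch_matrix()].
#' @return The window row with a `label` column added.
#' @export
classify_window <- function(window, tree, params, matrix) {
  stopifnot(nrow(window) == 1L, !is.null(window$vector))
  hit <- exists_within_k(
    tree, window$vector[[1L]], params$k, matrix,
    exclude_one_exact_self = params$self_exclude
  )
  dplyr::mutate(window, label = if (hit) "intersection" else "disjoint")
}

#' Split a window count into near-equal contiguous chunks
#'
#' Ranges are disjoint, cover `1..n_windows`, and their sizes differ by at
#' most one. Window classification is independent of its chunk, so output
#' merged in range order is identical for any thread count.
#'
#' @param n_windows number of windows.
#' @param threads number of chunks (at least 1).
#' @return A tibble with columns `start`, `end` (1-based, inclusive); zero
#'   rows when `n_windows` is 0.
#' @export
partition_workload <- function(n_windows, threads) {
  stopifnot(threads >= 1L, n_windows >= 0L)
  if (n_windows == 0L) {
    return(tibble(start = integer(), end = integer()))
  }
  threads <- min(as.integer(threads), n_windows)
  sizes <- rep(n_windows %/% threads, threads) +
    (seq_len(threads) <= n_windows %% threads)
  ends <- cumsum(sizes)
  tibble(start = ends - sizes + 1L, end = ends)
}

#' Classify every window of a query record set
#'
#' Extracts all W-length windows of every record (forward strand), encodes
#' them, and labels each `'disjoint'` or `'intersection'` against the taboo
#' index. Output is ordered by (source file, record order, position) and is
#' identical for any thread count.
#'
#' @param records a record tibble ([read_fasta_dir()] or the synthetic
#'   generators).
#' @param tree a `dictree` over the taboo set.
#' @param params a [scan_parameters()] object.
#' @param matrix the [mismatch_matrix()] for the shared scheme.
#' @return A tibble of window calls: `record_id`, `position`, `word`,
#'   `label`.
#' @export
scan_records <- function(records, tree, params, matrix) {
  stopifnot(inherits(tree, "dictree"), inherits(params, "scan_parameters"))
  scheme <- tree$scheme
  S <- scheme$sigma^scheme$N
  per_record <- lapply(seq_len(nrow(records)), function(r) {
    rec <- records[r, ]
    len <- nchar(rec$sequence)
    if (len < params$W) {
      warn(sprintf(
        "query record '%s' (length %d) is shorter than W = %d; no windows.",
        rec$record_id, len, params$W
      ))
      return(tibble(
        record_id = character(), position = integer(),
        word = character(), label = character()
      ))
    }
    starts <- seq_len(len - params$W + 1L)
    qmat <- encode_window_matrix(rec$sequence, starts, params$W, scheme)
    hit <- scan_code_matrix(qmat, tree, params, matrix, S)
    tibble(
      record_id = rec$record_id,
      position = starts,
      word = substring(rec$sequence, starts, starts + params$W - 1L),
      label = ifelse(hit, "intersection", "disjoint")
    )
  })
  dplyr::bind_rows(per_record)
}

# dispatch the compiled scan over partition_workload() chunks, optionally in
# parallel worker processes; chunk results are concatenated in range order
scan_code_matrix <- function(qmat, tree, params, matrix, S) {
  run_chunk <- function(rows) {
    dictree_scan_cpp(
      qmat[rows, , drop = FALSE], tree$sorted, tree$ukeys, tree$starts,
      unclass_matrix(matrix), S, params$k, params$self_exclude
    )
  }
  chunks <- partition_workload(nrow(qmat), params$threads)
  if (nrow(chunks) == 0L) {
    return(logical(0))
  }
  row_sets <- lapply(seq_len(nrow(chunks)), function(cc) {
    chunks$start[[cc]]:chunks$end[[cc]]
  })
  use_fork <- params$threads > 1L && .Platform$OS.type == "unix"
  results <- if (use_fork) {
    parallel::mclapply(row_sets, run_chunk, mc.cores = params$threads)
  } else {
    lapply(row_sets, run_chunk)
  }
  unlist(results, use.names = FALSE)
}

unclass_matrix <- function(M) {
  attr(M, "scheme") <- NULL
  class(M) <- NULL
  M
}
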