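#' Run a full k-disjoint scan of a query directory against a taboo directory
#'
#' Orchestrates the whole pipeline: read both FASTA directories, fragment
#' and encode the taboo windows (both strands), build the two-level index,
#' classify every query window, and summarize. The scan is exhaustive: a
#' window is reported `'disjoint'` only if **no** taboo window on either
#' strand lies within `k` mismatches.
#'
#' @param query_dir directory of query FASTA files (set A).
#' @param taboo_dir directory of taboo FASTA files (set B).
#' @param W window length (multiple of 3, 4 or 5; at least two blocks).
#' @param k mismatch threshold.
#' @param mode `'d'`, `'i'` or `'a'` — which label(s) [write_results()]
#'   emits.
#' @param self_exclude discount one exact self occurrence per window; turn
#'   on when the same genome sits in both directories (uniqueness mining,
#'   e.g. CRISPR target pre-filtering).
#' @param threads worker processes for the scan.
#' @param alphabet scheme alphabet (default the five-letter DNA alphabet).
#' @return An object of class `taboo_scan`: list with `calls` (tibble:
#'   `source_file`, `record_id`, `position`, `word`, `label`), `params`,
#'   `scheme`, and `summary` (see [glance.taboo_scan()]).
#' @examples
#' \donttest{
#' qd <- tempfile(); td <- tempfile()
#' write_fixture(generate_genome(400, seed = 1), qd, "query.fa")
#' write_fixture(generate_genome(2000, seed = 2), td, "taboo.fa")
#' scan <- run_taboo_scan(qd, td, W = 12, k = 1)
#' glance(scan)
#' }
#' @export
run_taboo_scan <- function(query_dir, taboo_dir, W, k, mode = "d",
                           self_exclude = FALSE, threads = 1L,
                           alphabet = c("A", "C", "G", "N", "T")) {
  params <- scan_parameters(W, k, mode,
    self_exclude = self_exclude, threads = threads
  )
  scheme <- encoding_scheme(params$N, alphabet)
  query <- read_fasta_dir(query_dir)
  taboo <- read_fasta_dir(taboo_dir)
  if (self_exclude && normalizePath(query_dir) == normalizePath(taboo_dir)) {
    message("self-comparison run: query and taboo directories are identical.")
  }
  M <- mismatch_matrix(scheme)
  tvecs <- fragment_taboo(taboo, params$W, scheme)
  tree <- build_dictree(tvecs, scheme, params$W)
  calls <- scan_with_sources(query, tree, params, M)
  structure(
    list(
      calls = calls,
      params = params,
      scheme = scheme,
      taboo_index_size = tree$n,
      n_taboo_sublists = length(tree$ukeys),
      query_length = sum(nchar(query$sequence)),
      summary = summarize_calls(calls, query, params)
    ),
    class = "taboo_scan"
  )
}

# scan_records() per source file so calls keep their originating file
scan_with_sources <- function(query, tree, params, M) {
  per_file <- lapply(unique(query$source_file), function(f) {
    recs <- query[query$source_file %in% f, ]
    calls <- scan_records(recs, tree, params, M)
    if (nrow(calls) > 0L) calls$source_file <- f else calls$source_file <- character(0)
    dplyr::select(
      calls, "source_file", "record_id", "position", "word", "label"
    )
  })
  dplyr::bind_rows(per_file)
}

# window-count fraction and genomic-territory fraction (union of disjoint
# window spans over total query length)
summarize_calls <- function(calls, query, params) {
  n_windows <- nrow(calls)
  n_disjoint <- sum(calls$label == "disjoint")
  disjoint <- calls[calls$label == "disjoint", ]
  territory <- 0L
  if (nrow(disjoint) > 0L) {
    by_rec <- split(disjoint$position, disjoint$record_id)
    territory <- sum(vapply(by_rec, function(p) {
      rng <- IRanges::IRanges(start = p, width = params$W)
      sum(IRanges::width(IRanges::reduce(rng)))
    }, numeric(1)))
  }
  total_len <- sum(nchar(query$sequence))
  tibble(
    n_windows = n_windows,
    n_disjoint = n_disjoint,
    n_intersection = n_windows - n_disjoint,
    frac_disjoint = if (n_windows > 0L) n_disjoint / n_windows else NA_real_,
    territory_disjoint = as.integer(territory),
    frac_territory = if (total_len > 0L) territory / total_len else NA_real_,
    W = params$W, N = params$N, k = params$k,
    self_exclude = params$self_exclude
  )
}

#' @export
print.taboo_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<taboo_scan> W = %d (N = %d), k = %d%s\n",
      "  %d query windows: %d disjoint (%.1f%%), %d intersecting\n",
      "  disjoint territory: %d bp (%.1f%% of query)\n",
      "  taboo index: %d vectors in %d sub-lists\n"
    ),
    s$W, s$N, s$k, if (s$self_exclude) ", self-exclusion on" else "",
    s$n_windows, s$n_disjoint, 100 * s$frac_disjoint, s$n_intersection,
    s$territory_disjoint, 100 * s$frac_territory,
    x$taboo_index_size, x$n_taboo_sublists
  ))
  invisible(x)
}

#' Tidy a taboo scan into its window calls
#'
#' @param x a `taboo_scan`.
#' @param ... unused.
#' @return The window-call tibble (`source_file`, `record_id`, `position`,
#'   `word`, `label`), one row per query window.
#' @method tidy taboo_scan
#' @export
tidy.taboo_scan <- function(x, ...) {
  x$calls
}

#' One-row summary of a taboo scan
#'
#' Reports both the window-count disjoint fraction and the genomic-territory
#' fraction (union of disjoint window spans over total query length) — the
#' two figures typically quoted for uniqueness scans.
#'
#' @param x a `taboo_scan`.
#' @param ... unused.
#' @return A one-row tibble.
#' @method glance taboo_scan
#' @export
glance.taboo_scan <- function(x, ...) {
  x$summary
}

#' Plot disjoint-window density along the query records
#'
#' Windows are binned along each record and the disjoint fraction per bin is
#' drawn, one facet per record — planted mutations and insertions show up as
#' spikes against an otherwise flat profile.
#'
#' @param object a `taboo_scan`.
#' @param bins approximate number of position bins per record.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot taboo_scan
#' @export
autoplot.taboo_scan <- function(object, bins = 200, ...) {
  calls <- object$calls
  if (nrow(calls) == 0L) {
    abort("nothing to plot: the scan produced no window calls.")
  }
  binned <- calls |>
    dplyr::group_by(.data$record_id) |>
    dplyr::mutate(bin = cut(.data$position, breaks = min(bins, dplyr::n()))) |>
    dplyr::group_by(.data$record_id, .data$bin) |>
    dplyr::summarise(
      position = mean(.data$position),
      frac_disjoint = mean(.data$label == "disjoint"),
      .groups = "drop"
    )
  ggplot2::ggplot(binned, ggplot2::aes(.data$position, .data$frac_disjoint)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::facet_wrap(ggplot2::vars(.data$record_id), ncol = 1L) +
    ggplot2::labs(
      x = "window start position", y = "fraction of windows k-disjoint",
      title = sprintf(
        "k-disjoint windows (W = %d, k = %d)",
        object$params$W, object$params$k
      )
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Write window calls as per-query-file TSV
#'
#' One TSV per query FASTA file. Mode `'d'` writes only disjoint calls,
#' `'i'` only intersecting ones, `'a'` writes both as `<stem>.disjoint.tsv`
#' and `<stem>.intersection.tsv`. Columns are `record_id`, `position`
#' (1-based window start) and `sequence`; commented header lines record W,
#' k, N, mode and the package version, so re-running an identical
#' configuration reproduces byte-identical files.
#'
#' @param scan a `taboo_scan` (or a window-call tibble with a `source_file`
#'   column).
#' @param output_dir directory to write into (created if needed).
#' @param mode overrides the scan's mode if given.
#' @param bed also write a BED file (0-based half-open window spans) per
#'   label for downstream probe/CRISPR design.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(scan, output_dir, mode = NULL, bed = FALSE) {
  if (inherits(scan, "taboo_scan")) {
    calls <- scan$calls
    params <- scan$params
    if (is.null(mode)) mode <- params$mode
  } else {
    calls <- scan
    params <- NULL
    if (is.null(mode)) mode <- "d"
  }
  stopifnot(mode %in% c("d", "i", "a"))
  ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) {
    abort(sprintf("cannot create output directory '%s'.", output_dir))
  }
  header <- sprintf(
    "# tabooscan %s | W=%s k=%s N=%s mode=%s self_exclude=%s",
    as.character(utils::packageVersion("tabooscan")),
    params$W %||% "?", params$k %||% "?", params$N %||% "?", mode,
    params$self_exclude %||% "?"
  )
  wanted <- switch(mode,
    d = "disjoint", i = "intersection", a = c("disjoint", "intersection")
  )
  paths <- character(0)
  for (f in unique(calls$source_file)) {
    stem <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", f, ignore.case = TRUE)
    fc <- calls[calls$source_file %in% f, ]
    for (lab in wanted) {
      suffix <- if (mode == "a") paste0(".", lab, ".tsv") else ".tsv"
      path <- file.path(output_dir, paste0(stem, suffix))
      sel <- fc[fc$label == lab, ]
      lines <- c(
        header,
        "# record_id\tposition\tsequence",
        sprintf("%s\t%d\t%s", sel$record_id, sel$position, sel$word)
      )
      writeLines(lines, path)
      paths <- c(paths, path)
      if (bed) {
        bed_path <- file.path(output_dir, paste0(stem, ".", lab, ".bed"))
        W <- params$W %||% nchar(sel$word[1] %||% "")
        bed_lines <- sprintf(
          "%s\t%d\t%d\t%s", sel$record_id, sel$position - 1L,
          sel$position - 1L + as.integer(W), lab
        )
        writeLines(bed_lines, bed_path)
        paths <- c(paths, bed_path)
      }
    }
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
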