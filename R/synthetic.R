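#' Generate a random genome record
#'
#' Letters are drawn i.i.d. uniformly from A/C/G/T; identical
#' `(length, seed)` pairs reproduce the identical sequence, so every
#' simulated experiment can be replayed bit for bit.
#'
#' @param length genome length in bases (at least 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param record_id record name (default derived from length and seed).
#' @return A one-row record tibble (`source_file`, `record_id`, `sequence`).
#' @export
generate_genome <- function(length, seed = NULL, record_id = NULL) {
  if (!is.numeric(length) || length(length) != 1L || length < 1) {
    abort("`length` must be a positive integer.")
  }
  length <- as.integer(length)
  draw <- function() {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }
  sequence <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (is.null(record_id)) {
    record_id <- sprintf("synth_%d%s", length,
                         if (is.null(seed)) "" else paste0("_s", seed))
  }
  tibble(source_file = NA_character_, record_id = record_id, sequence = sequence)
}

# transition map used for all planted substitutions
transition <- function(letters) chartr("AGCT", "GATC", letters)

#' Plant transition substitutions at given positions
#'
#' At each position the base is swapped by the transition map A<->G, C<->T.
#' An N at a planned site is left unchanged with a warning (it has no
#' transition partner). All other positions are untouched.
#'
#' @param record a one-row record tibble.
#' @param positions distinct 1-based positions within the record.
#' @return A list with elements `record` (mutated) and `plan` (a tibble with
#'   columns `record_id`, `kind`, `position`, `length`, `detail`).
#' @export
inject_substitutions <- function(record, positions) {
  stopifnot(nrow(record) == 1L)
  len <- nchar(record$sequence)
  positions <- as.integer(positions)
  if (anyDuplicated(positions) || any(positions < 1L | positions > len)) {
    abort("`positions` must be distinct and within the record.")
  }
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1L]]
  skipped <- positions[chars[positions] == "N"]
  if (length(skipped) > 0L) {
    warn(sprintf(
      "position(s) %s hold N and have no transition partner; left unchanged.",
      paste(skipped, collapse = ", ")
    ))
  }
  chars[positions] <- transition(chars[positions])
  out <- record
  out$sequence <- paste(chars, collapse = "")
  plan <- tibble(
    record_id = record$record_id,
    kind = "substitution",
    position = sort(positions),
    length = 1L,
    detail = ifelse(sort(positions) %in% skipped, "skipped_N", "transition")
  )
  list(record = out, plan = plan)
}

#' Invert a genomic segment in place
#'
#' The segment `[position, position + length - 1]` is replaced by its
#' reverse complement; flanks are untouched. Applying the same inversion
#' twice restores the original record.
#'
#' @param record a one-row record tibble.
#' @param position 1-based segment start.
#' @param length segment length.
#' @return A list with `record` (mutated) and `plan`.
#' @export
inject_inversion <- function(record, position, length) {
  stopifnot(nrow(record) == 1L)
  len <- nchar(record$sequence)
  position <- as.integer(position)
  length <- as.integer(length)
  if (position < 1L || length < 1L || position + length - 1L > len) {
    abort("inversion segment out of record bounds.")
  }
  seg <- substring(record$sequence, position, position + length - 1L)
  out <- record
  out$sequence <- paste0(
    substring(record$sequence, 1L, position - 1L),
    reverse_complement(seg),
    substring(record$sequence, position + length, len)
  )
  plan <- tibble(
    record_id = record$record_id, kind = "inversion",
    position = position, length = length, detail = seg
  )
  list(record = out, plan = plan)
}

#' Splice a (possibly mutated) donor sequence into a record
#'
#' The donor, with `n_mutations` of its positions transition-mutated (chosen
#' by `seed`), is inserted before the base at `position`; the result is
#' `nchar(donor)` longer than the original.
#'
#' @param record a one-row record tibble.
#' @param position 1-based insertion point (1 to record length + 1).
#' @param donor non-empty donor sequence.
#' @param n_mutations number of donor positions to transition-mutate
#'   (0 to donor length).
#' @param seed integer seed for the mutated-position draw.
#' @return A list with `record` (mutated) and `plan`; `plan$detail` holds
#'   the spliced (post-mutation) donor.
#' @export
inject_insertion <- function(record, position, donor, n_mutations = 0L,
                             seed = NULL) {
  stopifnot(nrow(record) == 1L, nchar(donor) >= 1L)
  len <- nchar(record$sequence)
  position <- as.integer(position)
  if (position < 1L || position > len + 1L) {
    abort("insertion point out of record bounds.")
  }
  n_mutations <- as.integer(n_mutations)
  stopifnot(n_mutations >= 0L, n_mutations <= nchar(donor))
  dchars <- strsplit(donor, "", fixed = TRUE)[[1L]]
  if (n_mutations > 0L) {
    pick <- function() sample.int(length(dchars), n_mutations)
    sites <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
    dchars[sites] <- transition(dchars[sites])
  }
  spliced <- paste(dchars, collapse = "")
  out <- record
  out$sequence <- paste0(
    substring(record$sequence, 1L, position - 1L),
    spliced,
    substring(record$sequence, position, len)
  )
  plan <- tibble(
    record_id = record$record_id, kind = "insertion",
    position = position, length = nchar(donor), detail = spliced
  )
  list(record = out, plan = plan)
}

#' Naive letter-by-letter k-disjoint reference
#'
#' The ground-truth oracle: every query window is compared positionwise to
#' every window of every taboo sequence (reverse complements included),
#' stopping a comparison once `k` is exceeded. No encoding, no index, no
#' pruning — quadratic, for verification at small scale only.
#'
#' @param query_records,taboo_records record tibbles.
#' @param W window length.
#' @param k mismatch threshold.
#' @return A window-call tibble (`record_id`, `position`, `word`, `label`)
#'   with the same ordering contract as [scan_records()].
#' @export
brute_force_kdisjoint <- function(query_records, taboo_records, W, k) {
  taboo_seqs <- character(0)
  if (nrow(taboo_records) > 0L) {
    fwd <- sanitize(taboo_records$sequence)
    taboo_seqs <- c(fwd, reverse_complement(fwd))
  }
  per_record <- lapply(seq_len(nrow(query_records)), function(r) {
    rec <- query_records[r, ]
    seqs <- sanitize(rec$sequence)
    len <- nchar(seqs)
    if (len < W) {
      return(tibble(
        record_id = character(), position = integer(),
        word = character(), label = character()
      ))
    }
    starts <- seq_len(len - W + 1L)
    words <- substring(seqs, starts, starts + W - 1L)
    hit <- brute_window_scan_cpp(words, taboo_seqs, W, k)
    tibble(
      record_id = rec$record_id,
      position = starts,
      word = words,
      label = ifelse(hit, "intersection", "disjoint")
    )
  })
  dplyr::bind_rows(per_record)
}

#' Which planted sites were recovered by disjoint windows?
#'
#' A planned site counts as recovered when at least one disjoint-labeled
#' window overlaps it. For substitutions the site is a single base; for
#' inversions and insertions it is the planted segment (positions taken in
#' the mutated record's coordinates). A window starting at `p` spans
#' `[p, p + W - 1]`, so overlap means
#' `p` in `[site_start - W + 1, site_end]`.
#'
#' @param calls a window-call tibble from a mutated-query-vs-original-taboo
#'   run.
#' @param plan a mutation plan tibble.
#' @param W the window length of the run.
#' @return The plan with columns `n_windows` (overlapping disjoint windows)
#'   and `recovered` added.
#' @export
recovered_sites <- function(calls, plan, W) {
  disjoint <- dplyr::filter(calls, .data$label == "disjoint")
  counts <- purrr::map_int(seq_len(nrow(plan)), function(s) {
    site_start <- plan$position[[s]]
    site_end <- site_start + plan$length[[s]] - 1L
    sum(
      disjoint$record_id == plan$record_id[[s]] &
        disjoint$position >= site_start - W + 1L &
        disjoint$position <= site_end
    )
  })
  dplyr::mutate(plan, n_windows = counts, recovered = counts >= 1L)
}

#' Write records and a mutation plan as plain-text fixtures
#'
#' Emits one FASTA file per distinct `source_file`/record and a TSV of the
#' mutation plan, so a simulated experiment is fully replayable from disk.
#'
#' @param records a record tibble.
#' @param dir output directory (created if needed).
#' @param file_name FASTA file name.
#' @param plan optional plan tibble; written as `plan.tsv` alongside.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(records, dir, file_name = "records.fa", plan = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, file_name)
  lines <- unlist(lapply(seq_len(nrow(records)), function(r) {
    s <- records$sequence[[r]]
    from <- seq(1L, nchar(s), by = 70L)
    c(paste0(">", records$record_id[[r]]),
      substring(s, from, pmin(from + 69L, nchar(s))))
  }))
  writeLines(lines, fa)
  paths <- fa
  if (!is.null(plan)) {
    tsv <- file.path(dir, "plan.tsv")
    utils::write.table(plan, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, tsv)
  }
  invisible(paths)
}
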