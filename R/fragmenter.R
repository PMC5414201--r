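#' Read a directory of FASTA files into a record table
#'
#' Every record of every FASTA file (extensions `.fa`, `.fasta`, `.fna`,
#' optionally gzipped) is returned as one row, in file order then record
#' order. Sequences are sanitized: uppercased, with any character outside
#' A/C/G/T (IUPAC ambiguity codes, gaps, stray symbols) replaced by the
#' canonical unknown base N. Record ids are the first whitespace-delimited
#' token of the header line.
#'
#' @param path directory containing at least one FASTA file.
#' @return A tibble with columns `source_file`, `record_id`, `sequence`.
#' @export
read_fasta_dir <- function(path) {
  if (!dir.exists(path)) {
    abort(sprintf("directory '%s' does not exist.", path))
  }
  files <- list.files(path,
    pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
    full.names = TRUE, ignore.case = TRUE
  )
  if (length(files) == 0L) {
    abort(sprintf("no FASTA files (.fa/.fasta/.fna[.gz]) found in '%s'.", path))
  }
  purrr::map_dfr(sort(files), read_fasta_file)
}

read_fasta_file <- function(file) {
  check_fasta_starts_with_header(file)
  set <- Biostrings::readBStringSet(file)
  ids <- vapply(
    strsplit(names(set), "[ \t]+"),
    function(x) x[[1L]], character(1)
  )
  tibble(
    source_file = basename(file),
    record_id = ids,
    sequence = sanitize(unname(as.character(set)))
  )
}

# reject sequence data appearing before the first '>' header, naming the spot
check_fasta_starts_with_header <- function(file) {
  con <- if (grepl("\\.gz$", file)) gzfile(file, "rt") else file(file, "rt")
  on.exit(close(con))
  lineno <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) {
      abort(sprintf("'%s' contains no FASTA records.", file))
    }
    lineno <- lineno + 1L
    if (nzchar(trimws(line))) break
  }
  if (!startsWith(trimws(line), ">")) {
    abort(sprintf(
      "malformed FASTA: '%s' line %d has sequence before the first header.",
      file, lineno
    ))
  }
  invisible(TRUE)
}

#' Sanitize a DNA sequence to the five-letter alphabet
#'
#' Uppercases and replaces every character outside A/C/G/T by N. Length is
#' preserved, so downstream coordinates refer to the original sequence.
#'
#' @param raw character vector of sequences.
#' @return Character vector over \{A,C,G,N,T\} of the same lengths.
#' @examples
#' sanitize("acRgt-") # "ACNGTN"
#' @export
sanitize <- function(raw) {
  up <- toupper(raw)
  gsub("[^ACGT]", "N", up)
}

#' Reverse complement over the five-letter alphabet
#'
#' A<->T, C<->G, N<->N, order reversed. An involution:
#' `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param word character vector of sequences over \{A,C,G,N,T\}.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AACG") # "CGTT"
#' @export
reverse_complement <- function(word) {
  flipped <- chartr("ACGTN", "TGCAN", word)
  vapply(flipped, function(w) {
    paste(rev(strsplit(w, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract all W-length windows of a record
#'
#' One window per start position `1 .. nchar(sequence) - W + 1`, forward
#' strand only. A record shorter than `W` yields zero windows with a warning
#' rather than an error, so mixed-length directories run to completion.
#'
#' @param record a one-row record tibble (columns `record_id`, `sequence`,
#'   optionally `source_file`).
#' @param W window length.
#' @param scheme optional [encoding_scheme()]; when supplied a `vector`
#'   list-column of integer code vectors is attached.
#' @return A tibble with columns `record_id`, `position`, `word` (and
#'   `vector` when `scheme` is given).
#' @export
extract_windows <- function(record, W, scheme = NULL) {
  stopifnot(nrow(record) == 1L)
  len <- nchar(record$sequence)
  if (len < W) {
    warn(sprintf(
      "record '%s' (length %d) is shorter than W = %d; no windows extracted.",
      record$record_id, len, W
    ))
    out <- tibble(
      record_id = character(), position = integer(), word = character()
    )
    if (!is.null(scheme)) out$vector <- list()
    return(out)
  }
  starts <- seq_len(len - W + 1L)
  out <- tibble(
    record_id = record$record_id,
    position = starts,
    word = substring(record$sequence, starts, starts + W - 1L)
  )
  if (!is.null(scheme)) {
    mat <- encode_window_matrix(record$sequence, starts, W, scheme)
    out$vector <- lapply(seq_len(nrow(mat)), function(r) mat[r, ])
  }
  out
}

# Integer code matrix (one row per window, W/N columns of 0-based codes) for
# windows starting at `starts`. Block codes at every offset are computed once
# for the whole sequence, then gathered per window.
encode_window_matrix <- function(sequence, starts, W, scheme) {
  N <- scheme$N
  Lv <- W %/% N
  if (length(starts) == 0L) {
    return(matrix(integer(), 0L, Lv))
  }
  d <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], scheme$alphabet) - 1L
  if (anyNA(d)) {
    abort("sequence contains letters outside the scheme alphabet; sanitize first.")
  }
  n_grams <- length(d) - N + 1L
  codes <- numeric(n_grams)
  pow <- scheme$sigma^((N - 1L):0L)
  for (p in seq_len(N)) {
    codes <- codes + d[p:(p + n_grams - 1L)] * pow[p]
  }
  idx <- outer(starts, (0:(Lv - 1L)) * N, "+")
  mat <- matrix(as.integer(codes[idx]), nrow = length(starts), ncol = Lv)
  mat
}

#' Fragment a taboo record set into encoded window vectors
#'
#' Extracts every W-length window of every record — reverse complement
#' strand included — and encodes each as a `W/N` integer code vector. The
#' result feeds [build_dictree()]. Total rows equal
#' `2 * sum(max(0, len_r - W + 1))`.
#'
#' @param records a record tibble as returned by [read_fasta_dir()].
#' @param W window length.
#' @param scheme an [encoding_scheme()].
#' @param include_rc include the reverse-complement strand (default TRUE,
#'   as the indexing step prescribes; exposed for testing).
#' @return An integer matrix, one encoded window vector per row.
#' @export
fragment_taboo <- function(records, W, scheme, include_rc = TRUE) {
  Lv <- W %/% scheme$N
  pieces <- list()
  for (r in seq_len(nrow(records))) {
    seqs <- records$sequence[[r]]
    len <- nchar(seqs)
    if (len < W) {
      warn(sprintf(
        "taboo record '%s' (length %d) is shorter than W = %d; skipped.",
        records$record_id[[r]], len, W
      ))
      next
    }
    starts <- seq_len(len - W + 1L)
    pieces[[length(pieces) + 1L]] <-
      encode_window_matrix(seqs, starts, W, scheme)
    if (include_rc) {
      pieces[[length(pieces) + 1L]] <-
        encode_window_matrix(reverse_complement(seqs), starts, W, scheme)
    }
  }
  if (length(pieces) == 0L) {
    return(matrix(integer(), 0L, Lv))
  }
  do.call(rbind, pieces)
}
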