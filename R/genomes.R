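#' Normalize a DNA sequence to the {A,C,G,T,N} alphabet
#'
#' Uppercases the sequence, strips whitespace, and maps every IUPAC
#' ambiguity code other than A/C/G/T to `N`. In strict mode any character
#' outside A/C/G/T/N (after case folding) is an error instead.
#'
#' Normalization is idempotent: applying it to an already normalized
#' sequence changes nothing.
#'
#' @param x Character vector of DNA sequences.
#' @param strict If `TRUE`, reject ambiguity codes instead of mapping to `N`.
#' @return Character vector of normalized sequences.
#' @export
#' @examples
#' normalize_sequence("acg tRn")
normalize_sequence <- function(x, strict = FALSE) {
  x <- toupper(gsub("[ \t\r\n]", "", x))
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    if (strict) {
      stop_validation(sprintf(
        "sequence contains non-ACGTN characters (strict mode): e.g. %s",
        sub(".*?([^ACGTN]).*", "\\1", x[bad][1])
      ))
    }
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  }
  x
}

#' Read genomes from a FASTA file
#'
#' Parses a (multi-)FASTA file into a genome table. Record ids are the first
#' whitespace-delimited token of each header; the full header is kept as the
#' description. Sequences are uppercased and non-ACGTN IUPAC codes are
#' mapped to `N` (or rejected with `strict = TRUE`).
#'
#' @param path Path to a FASTA file.
#' @param strict Reject ambiguity codes instead of mapping them to `N`.
#' @return A tibble with columns `id`, `description`, `sequence`, `length`.
#'   Ids are guaranteed unique; duplicated ids are an error naming the
#'   duplicate.
#' @export
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "phagetools_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop_validation(sprintf("FASTA file is empty: %s", path))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop_parse(sprintf("not a FASTA file (first line lacks '>'): %s", path))
  }
  rec <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  ids <- sub("[ \t].*$", "", headers)
  if (any(!nzchar(ids))) stop_parse("FASTA header with empty id")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_validation(sprintf("duplicate FASTA id(s): %s", paste(dup, collapse = ", ")))
  }
  seqs <- vapply(
    split(lines[!is_header], factor(rec[!is_header], levels = seq_along(headers))),
    paste0, character(1), collapse = ""
  )
  seqs <- normalize_sequence(unname(seqs), strict = strict)
  if (any(!nzchar(seqs))) {
    stop_validation(sprintf(
      "record(s) with empty sequence: %s",
      paste(ids[!nzchar(seqs)], collapse = ", ")
    ))
  }
  tibble(
    id = ids,
    description = headers,
    sequence = seqs,
    length = nchar(seqs)
  )
}

#' Write genomes to a FASTA file
#'
#' @param genomes Genome tibble (columns `id`, `sequence`, optionally
#'   `description`).
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70) {
  assert_genomes(genomes)
  desc <- if ("description" %in% names(genomes)) genomes$description else genomes$id
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(genomes))) {
    writeLines(paste0(">", desc[i]), con)
    s <- genomes$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a tip-metadata table from CSV
#'
#' Reads a comma-separated metadata table keyed by a label column (for
#' example a `sample_info.csv` holding taxonomy for each tree tip). All
#' columns are read as character; the label column is moved first.
#'
#' @param path Path to a CSV file with a header row.
#' @param label_column Name of the column holding the tip labels.
#' @return A tibble whose first column is `label_column`; labels are unique.
#' @export
read_metadata_csv <- function(path, label_column) {
  if (!file.exists(path)) {
    abort(sprintf("metadata file not found: %s", path), class = "phagetools_io_error")
  }
  meta <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, show_col_types = FALSE)
  if (!label_column %in% names(meta)) {
    stop_validation(sprintf(
      "label column `%s` not found; columns present: %s",
      label_column, paste(names(meta), collapse = ", ")
    ))
  }
  labs <- meta[[label_column]]
  if (anyDuplicated(labs)) {
    dup <- unique(labs[duplicated(labs)])
    stop_validation(sprintf("duplicate label(s) in metadata: %s", paste(dup, collapse = ", ")))
  }
  dplyr::relocate(meta, dplyr::all_of(label_column))
}
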