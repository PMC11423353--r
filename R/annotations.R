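annotation_cols <- c("source", "contig_id", "feature_type", "start", "end",
                     "strand", "product", "nt_seq", "aa_seq")

new_annotation_set <- function(df, source) {
  df <- as_tibble(df)
  for (col in setdiff(annotation_cols, names(df))) df[[col]] <- NA_character_
  df <- df[annotation_cols]
  df$source <- source
  if (any(df$start < 1L)) stop_validation("annotation with start < 1")
  if (any(df$end < df$start)) stop_validation("annotation with end < start")
  if (!all(df$strand %in% c("+", "-"))) stop_validation("invalid strand value")
  key <- paste(df$start, df$end, df$strand)
  if (anyDuplicated(key)) {
    stop_validation(sprintf(
      "duplicate (start, end, strand) in %s set: %s",
      source, key[duplicated(key)][1L]
    ))
  }
  if (length(unique(df$contig_id)) > 1L) {
    stop_validation("annotation set spans multiple contigs")
  }
  class(df) <- c("annotation_set", class(df))
  df
}

#' Parse a Pharokka-style GFF3 annotation file
#'
#' Reads the nine-column GFF3 body; the `product` is extracted from the
#' attributes column. Coordinates stay 1-based inclusive. Non-CDS rows
#' (e.g. tRNA) are retained with their feature type.
#'
#' @param path GFF3 file path.
#' @return An `annotation_set` tibble (columns `source`, `contig_id`,
#'   `feature_type`, `start`, `end`, `strand`, `product`, `nt_seq`,
#'   `aa_seq`).
#' @export
parse_pharokka_gff <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("GFF file not found: %s", path), class = "phagetools_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (grepl("##FASTA", paste(lines, collapse = "\n"), fixed = TRUE)) {
    fasta_at <- which(startsWith(lines, "##FASTA"))[1L]
    body_idx <- body_idx[body_idx < fasta_at]
  }
  if (!length(body_idx)) stop_parse(sprintf("no feature rows in %s", path))
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) {
      stop_parse(sprintf("%s line %d: expected 9 tab-separated columns, got %d",
                         path, i, length(f)))
    }
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end)) {
      stop_parse(sprintf("%s line %d: non-numeric coordinates", path, i))
    }
    if (end < start) {
      stop_parse(sprintf("%s line %d: end (%d) < start (%d)", path, i, end, start))
    }
    product <- sub(".*product=([^;]*).*", "\\1", f[9L])
    if (identical(product, f[9L])) product <- NA_character_
    tibble(contig_id = f[1L], feature_type = f[3L], start = start, end = end,
           strand = if (f[7L] == "-") "-" else "+",
           product = product)
  })
  new_annotation_set(dplyr::bind_rows(rows), "pharokka")
}

#' Parse a PHASTER-style region-detail text file
#'
#' Rows are whitespace-delimited and must carry a coordinate token
#' `start..end` or `complement(start..end)` (the latter gives strand `-`);
#' the remaining annotation phrase becomes the product. Header and
#' comment lines, and rows without a parsable coordinate token, are
#' skipped with a warning; a file with zero parsable rows is a parse
#' error.
#'
#' @param path Text file path.
#' @return An `annotation_set` tibble.
#' @export
parse_phaster_txt <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("PHASTER file not found: %s", path), class = "phagetools_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  coord_re <- "(complement\\()?(\\d+)\\.\\.(\\d+)\\)?"
  rows <- list()
  skipped <- 0L
  for (ln in lines) {
    m <- regexec(coord_re, ln)[[1L]]
    if (m[1L] == -1L) { skipped <- skipped + 1L; next }
    g <- regmatches(ln, list(m))[[1L]]
    start <- as.integer(g[3L]); end <- as.integer(g[4L])
    strand <- if (nzchar(g[2L])) "-" else "+"
    # the annotation phrase is whatever follows the coordinate token
    rest <- trimws(substring(ln, m[1L] + attr(m, "match.length")[1L]))
    rows[[length(rows) + 1L]] <- tibble(
      contig_id = "region", feature_type = "CDS",
      start = min(start, end), end = max(start, end), strand = strand,
      product = if (nzchar(rest)) rest else NA_character_
    )
  }
  if (!length(rows)) {
    stop_parse(sprintf("no coordinate-bearing rows found in %s", path))
  }
  if (skipped > 0L) {
    warn(sprintf("%s: skipped %d row(s) without a parsable coordinate token",
                 path, skipped))
  }
  new_annotation_set(dplyr::bind_rows(rows), "phaster")
}

#' Parse a RAST tab-separated annotation export
#'
#' Expects a header row with `start`, `stop`, `strand` and `function`
#' columns (the tab-separated export of the RAST spreadsheet; binary
#' spreadsheets must be pre-exported). Start/stop are re-oriented so that
#' start <= end; the `function` column becomes the product.
#'
#' @param path TSV file path.
#' @return An `annotation_set` tibble.
#' @export
parse_rast_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("RAST file not found: %s", path), class = "phagetools_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, show_col_types = FALSE)
  names(df) <- tolower(names(df))
  required <- c("start", "stop", "strand", "function")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_validation(sprintf(
      "RAST table %s is missing required column(s): %s (is it tab-separated?)",
      path, paste(missing, collapse = ", ")
    ))
  }
  raw_start <- suppressWarnings(as.integer(df$start))
  raw_stop <- suppressWarnings(as.integer(df$stop))
  if (anyNA(raw_start) || anyNA(raw_stop)) {
    stop_parse(sprintf("%s: non-numeric start/stop values", path))
  }
  new_annotation_set(tibble(
    contig_id = if ("contig_id" %in% names(df)) df$contig_id else "contig",
    feature_type = if ("type" %in% names(df)) df$type else "CDS",
    start = pmin(raw_start, raw_stop), end = pmax(raw_start, raw_stop),
    strand = ifelse(df$strand %in% c("-", "minus"), "-", "+"),
    product = df[["function"]]
  ), "rast")
}
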