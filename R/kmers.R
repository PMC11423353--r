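#' Choose a k-mer length for a genome collection
#'
#' Heuristic default: `round(log4(median genome length))`, clamped to
#' `[6, 14]` — the k at which the 4^k feature space is comparable to the
#' number of k-mer windows per genome, standard practice for
#' feature-frequency-profile phylogenies. An explicit override bypasses the
#' heuristic after a bounds check.
#'
#' @param genomes Genome tibble (needs a `length` or `sequence` column).
#' @param override Optional integer k in `[1, 16]`.
#' @return Integer k.
#' @export
#' @examples
#' choose_k(tibble::tibble(id = "g", sequence = "ACGT", length = 50000))
choose_k <- function(genomes, override = NULL) {
  if (!is.null(override)) {
    override <- as.integer(override)
    if (length(override) != 1L || is.na(override) || override < 1L || override > 16L) {
      stop_parameter("k override must be a single integer in [1, 16]")
    }
    return(override)
  }
  if (nrow(genomes) == 0L) stop_parameter("need at least one genome to choose k")
  len <- if ("length" %in% names(genomes)) genomes$length else nchar(genomes$sequence)
  k <- round(log(stats::median(len), base = 4))
  as.integer(min(14L, max(6L, k)))
}

#' Count k-mers in genome sequences
#'
#' Counts every length-`k` window on the given strand whose characters are
#' all in `{A,C,G,T}`; windows containing `N` are skipped and do not
#' contribute to the total. Counting is single-strand by default, matching
#' the feature definition over the literal character sequence; with
#' `canonical = TRUE` each window is counted as the lexicographic minimum of
#' itself and its reverse complement.
#'
#' @param genomes Genome tibble (columns `id`, `sequence`), or a single
#'   character sequence.
#' @param k k-mer length (>= 1).
#' @param canonical Collapse each k-mer with its reverse complement.
#' @return A tibble with columns `genome_id`, `kmer`, `count` holding the
#'   nonzero counts (sparse), with attributes `k`. A genome shorter than `k`
#'   yields no rows (total 0), not an error.
#' @export
#' @examples
#' count_kmers(tibble::tibble(id = "g", sequence = "ACGNAC"), k = 2)
count_kmers <- function(genomes, k, canonical = FALSE) {
  if (is.character(genomes)) {
    genomes <- tibble(id = names(genomes) %||% paste0("seq", seq_along(genomes)),
                      sequence = unname(genomes))
  }
  assert_genomes(genomes)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop_parameter("k must be a positive integer")
  res <- purrr::map2(genomes$id, genomes$sequence, function(id, seq) {
    n <- nchar(seq) - k + 1L
    if (n < 1L) {
      return(tibble(genome_id = character(), kmer = character(), count = integer()))
    }
    win <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
    win <- win[!grepl("N", win, fixed = TRUE)]
    if (canonical && length(win)) {
      rc <- revcomp(win)
      win <- pmin(win, rc)
    }
    if (!length(win)) {
      return(tibble(genome_id = character(), kmer = character(), count = integer()))
    }
    tab <- table(win)
    tibble(genome_id = id, kmer = names(tab), count = as.integer(tab))
  })
  out <- dplyr::bind_rows(res)
  attr(out, "k") <- k
  out
}

#' Reverse complement of DNA strings
#' @param x Character vector over A/C/G/T/N.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Normalize k-mer counts to feature-frequency profiles
#'
#' Divides each genome's k-mer counts by that genome's total, turning the
#' count vector into a probability distribution over the 4^k k-mer feature
#' space (zero features stay implicit). Frequencies sum to 1 per genome
#' within 1e-12.
#'
#' @param counts Output of [count_kmers()] (columns `genome_id`, `kmer`,
#'   `count`), or a genome tibble, in which case `k` must be supplied and
#'   counting is performed first.
#' @param k k-mer length, only used when `counts` is a genome tibble.
#' @param ... Passed on to [count_kmers()] in that case.
#' @return A tibble `genome_id`, `kmer`, `freq` with attribute `k`.
#'   A genome with total 0 (too short, or all windows contain `N`) is a
#'   degenerate-input error.
#' @export
kmer_frequencies <- function(counts, k = NULL, ...) {
  if ("sequence" %in% names(counts)) {
    if (is.null(k)) stop_parameter("supply `k` when passing genomes directly")
    ids <- counts$id
    counts <- count_kmers(counts, k, ...)
    missing_ids <- setdiff(ids, unique(counts$genome_id))
    if (length(missing_ids)) {
      stop_validation(sprintf(
        "genome(s) with no countable %d-mers (too short or all-N): %s",
        k, paste(missing_ids, collapse = ", ")
      ))
    }
  }
  if (nrow(counts) == 0L) {
    stop_validation("no k-mer counts: genome too short or all-N for the chosen k")
  }
  out <- counts %>%
    dplyr::group_by(.data$genome_id) %>%
    dplyr::mutate(freq = .data$count / sum(.data$count)) %>%
    dplyr::ungroup() %>%
    dplyr::select("genome_id", "kmer", "freq")
  attr(out, "k") <- attr(counts, "k") %||% nchar(out$kmer[1L])
  out
}
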