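#' Six-frame translation into stop-free protein fragments
#'
#' Translates each genome in all six reading frames (three forward, three
#' on the reverse complement) with the bacterial/phage genetic code (table
#' 11 by default), splits each frame's translation at stop codons, and
#' keeps the maximal stop-free fragments of at least `min_aa` residues.
#' Codons containing `N` translate to `X`, and `X` is allowed inside
#' fragments.
#'
#' @param genomes Genome tibble (columns `id`, `sequence`).
#' @param min_aa Minimum fragment length in amino acids (default 40).
#' @param code_table NCBI genetic-code table number (default 11).
#' @return A tibble with columns `genome_id`, `frame` (one of
#'   `+1,+2,+3,-1,-2,-3` as integers), `start_nt` (1-based forward-strand
#'   position of the 5'-most nucleotide of the fragment's first codon on
#'   its own strand), `aa_seq`, `aa_length`. Genomes shorter than 3 nt
#'   yield no rows.
#' @export
six_frame_translate <- function(genomes, min_aa = 40L, code_table = 11L) {
  assert_genomes(genomes)
  if (min_aa < 1L) stop_parameter("min_aa must be >= 1")
  code <- Biostrings::getGeneticCode(as.character(code_table))

  frame_frags <- function(id, seqstr, frame_label, offset, L, reverse) {
    usable <- L - offset + 1L
    ncod <- usable %/% 3L
    if (ncod < 1L) return(NULL)
    sub <- substr(seqstr, offset, offset + 3L * ncod - 1L)
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(sub), genetic.code = code, if.fuzzy.codon = "X",
      no.init.codon = TRUE  # frame scan, not ORF calling: no initiator M
    ))
    m <- gregexpr("[^*]+", aa)[[1L]]
    if (m[1L] == -1L) return(NULL)
    len <- attr(m, "match.length")
    keep <- len >= min_aa
    if (!any(keep)) return(NULL)
    starts <- as.integer(m)[keep]
    len <- len[keep]
    start_in_strand <- offset + 3L * (starts - 1L)
    start_nt <- if (reverse) L - start_in_strand + 1L else start_in_strand
    tibble(
      genome_id = id,
      frame = frame_label,
      start_nt = start_nt,
      aa_seq = substring(aa, starts, starts + len - 1L),
      aa_length = len
    )
  }

  res <- purrr::map2(genomes$id, genomes$sequence, function(id, seq) {
    L <- nchar(seq)
    if (L < 3L) return(NULL)
    rc <- revcomp(seq)
    dplyr::bind_rows(
      purrr::map(1:3, ~ frame_frags(id, seq, .x, .x, L, reverse = FALSE)),
      purrr::map(1:3, ~ frame_frags(id, rc, -.x, .x, L, reverse = TRUE))
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble(genome_id = character(), frame = integer(),
                  start_nt = integer(), aa_seq = character(),
                  aa_length = integer())
  }
  out
}
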