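random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_genome_tbl <- function(n_genomes, length, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("g%02d", seq_len(n_genomes)),
    description = sprintf("g%02d", seq_len(n_genomes)),
    sequence = replicate(n_genomes, random_dna(length)),
    length = length
  )
}

# random unrooted topology with branch lengths in [lo, hi]
random_bl_tree <- function(ntips, lo = 0.01, hi = 2) {
  tr <- ape::rtree(ntips, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), lo, hi)
  tr
}

write_temp_fasta <- function(genomes) {
  tf <- tempfile(fileext = ".fasta")
  phagetools::write_fasta(genomes, tf)
  tf
}

# brute-force JSD from first principles, independent of the package path
jsd_brute <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- ifelse(keys %in% names(p), p[keys], 0)
  qv <- ifelse(keys %in% names(q), q[keys], 0)
  m <- (pv + qv) / 2
  h <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  h(m) - (h(pv) + h(qv)) / 2
}
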