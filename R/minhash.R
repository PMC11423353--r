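# Stable k-mer hash: base-4 code reduced by a fixed multiplicative hash
# modulo the Mersenne prime 2^31 - 1. Constants are fixed so sketches are
# reproducible across sessions and platforms; arithmetic stays exact in
# doubles (a * x < 2^51 < 2^53).
.mh_prime <- 2147483647
.mh_a <- 1048573
.mh_b <- 12345

kmer_code <- function(kmers) {
  k <- nchar(kmers[1L])
  digits <- matrix(match(unlist(strsplit(kmers, "", fixed = TRUE)),
                         c("A", "C", "G", "T")) - 1,
                   nrow = k)
  as.numeric(4^((k - 1):0) %*% digits)
}

mh_hash <- function(codes) {
  (.mh_a * (codes %% .mh_prime) + .mh_b) %% .mh_prime
}

#' Bottom-s MinHash sketch of a genome's k-mer set
#'
#' Hashes the genome's distinct (N-free, single-strand) k-mers with a fixed
#' multiplicative hash and keeps the `sketch_size` smallest values. This is
#' the optional sketching route to pairwise distances; the default pipeline
#' uses full frequency profiles and Jensen-Shannon divergence instead.
#'
#' @param genomes Genome tibble (columns `id`, `sequence`).
#' @param k k-mer length.
#' @param sketch_size Number of minimum hash values retained.
#' @return A list of sketches, one per genome: each a list with fields
#'   `genome_id`, `k`, `sketch_size`, `hashes` (sorted ascending, distinct).
#' @export
minhash_sketch <- function(genomes, k, sketch_size = 1000L) {
  assert_genomes(genomes)
  sketch_size <- as.integer(sketch_size)
  if (sketch_size < 1L) stop_parameter("sketch_size must be >= 1")
  counts <- count_kmers(genomes, k)
  lapply(genomes$id, function(id) {
    km <- counts$kmer[counts$genome_id == id]
    h <- sort(unique(mh_hash(kmer_code(km))))
    list(genome_id = id, k = as.integer(k), sketch_size = sketch_size,
         hashes = utils::head(h, sketch_size))
  })
}

#' MinHash-estimated Jaccard distance between two sketches
#'
#' Bottom-s estimator: over the `s` smallest hashes of the union of the two
#' sketches, the Jaccard index is estimated as the fraction also present in
#' both sketches; the distance is one minus that.
#'
#' @param a,b Sketches from [minhash_sketch()] with identical `k` and
#'   `sketch_size`.
#' @return Estimated Jaccard distance in `[0, 1]`.
#' @export
minhash_jaccard_distance <- function(a, b) {
  if (a$k != b$k) stop_parameter("sketches use different k")
  if (a$sketch_size != b$sketch_size) stop_parameter("sketches use different sketch_size")
  s <- min(a$sketch_size, length(a$hashes) + length(b$hashes))
  uni <- utils::head(sort(unique(c(a$hashes, b$hashes))), s)
  shared <- sum(uni %in% a$hashes & uni %in% b$hashes)
  1 - shared / length(uni)
}
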