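# Shannon entropy in bits; 0*log2(0) treated as 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon divergence between two frequency profiles
#'
#' `JS(p, q) = H(m) - (H(p) + H(q))/2` with `m = (p + q)/2`, entropies in
#' log base 2 over the union of nonzero features, so the result lies in
#' `[0, 1]`: 0 iff the profiles are equal, 1 iff their supports are
#' disjoint.
#'
#' @param p,q Named numeric vectors of feature frequencies (names are the
#'   k-mers; both must use the same k) each summing to 1.
#' @return The divergence, a number in `[0, 1]`.
#' @export
#' @examples
#' jensen_shannon(c(AA = 0.5, AC = 0.5), c(AA = 1))
jensen_shannon <- function(p, q) {
  if (is.null(names(p)) || is.null(names(q))) {
    stop_parameter("profiles must be named numeric vectors (names = k-mers)")
  }
  if (nchar(names(p)[1]) != nchar(names(q)[1])) {
    stop_parameter("profiles use different k-mer lengths")
  }
  keys <- union(names(p), names(q))
  pv <- unname(p[match(keys, names(p))]); pv[is.na(pv)] <- 0
  qv <- unname(q[match(keys, names(q))]); qv[is.na(qv)] <- 0
  m <- (pv + qv) / 2
  d <- entropy_bits(m) - (entropy_bits(pv) + entropy_bits(qv)) / 2
  min(max(d, 0), 1)  # guard rounding at the boundaries
}

#' Pairwise Jensen-Shannon distance matrix of frequency profiles
#'
#' @param freqs Long frequency tibble from [kmer_frequencies()] (columns
#'   `genome_id`, `kmer`, `freq`).
#' @return A symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`, dimnames set to the genome ids (in first-appearance order).
#' @export
jsd_matrix <- function(freqs) {
  ids <- unique(freqs$genome_id)
  if (length(ids) < 2L) stop_parameter("need at least two profiles")
  if (anyDuplicated(ids)) stop_validation("duplicate genome ids")
  if (length(unique(nchar(freqs$kmer))) != 1L) {
    stop_parameter("profiles use different k-mer lengths")
  }
  keys <- unique(freqs$kmer)
  # dense n x |union| matrix: small for realistic k, fast for all-pairs JSD
  mat <- matrix(0, nrow = length(ids), ncol = length(keys),
                dimnames = list(ids, NULL))
  mat[cbind(match(freqs$genome_id, ids), match(freqs$kmer, keys))] <- freqs$freq
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  h <- apply(mat, 1L, entropy_bits)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dij <- entropy_bits((mat[i, ] + mat[j, ]) / 2) - (h[i] + h[j]) / 2
      d[i, j] <- d[j, i] <- min(max(dij, 0), 1)
    }
  }
  d
}

#' Write a distance matrix as square CSV
#'
#' Labels appear as the first row and first column; values are written at
#' full double precision.
#'
#' @param d Symmetric labeled matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(d, path) {
  df <- tibble::as_tibble(d, rownames = "id")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a square distance CSV written by [write_distance_csv()]
#' @param path CSV path.
#' @return A labeled symmetric matrix.
#' @export
read_distance_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df[[1L]]
  m
}
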