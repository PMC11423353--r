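nwk_quote <- function(x) {
  needs <- grepl("[][ ():;,']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

nwk_num <- function(x) sprintf("%.12g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: iteratively joins the pair of nodes
#' minimizing the Q criterion `Q_ij = (n-2) d_ij - r_i - r_j` (with `r`
#' the row sums), computes pendant branch lengths by the standard
#' rate-corrected formulas, and reduces the matrix with
#' `d_uk = (d_ik + d_jk - d_ij)/2`. Ties in Q (within 1e-12) are broken by
#' the smallest `(i, j)` index pair, so the output is deterministic.
#' Negative branch lengths are clamped to 0. For an additive matrix the
#' generating tree is recovered exactly.
#'
#' @param d Symmetric numeric matrix with non-negative entries, zero
#'   diagonal, and row/column labels. Two labels give a single edge split
#'   evenly; three give the closed-form star resolution.
#' @return An unrooted tree of class [ape::phylo] with all input labels as
#'   tips.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop_validation("distance matrix must be square")
  labels <- rownames(d) %||% colnames(d)
  if (is.null(labels)) stop_validation("distance matrix must carry labels")
  if (nrow(d) < 2L) stop_parameter("need at least 2 taxa")
  if (any(d < 0)) stop_validation("distance matrix has negative entries")
  if (any(abs(d - t(d)) > 1e-8)) stop_validation("distance matrix is asymmetric")
  if (any(abs(diag(d)) > 1e-12)) stop_validation("distance matrix has nonzero diagonal")

  frag <- nwk_quote(labels)
  dm <- d
  while (nrow(dm) > 3L) {
    n <- nrow(dm)
    r <- rowSums(dm)
    q <- (n - 2) * dm - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- dm[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- dm[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    dnew <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    merged <- sprintf("(%s:%s,%s:%s)", frag[i], nwk_num(li), frag[j], nwk_num(lj))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    frag <- c(frag[keep], merged)
  }
  nwk <- if (nrow(dm) == 2L) {
    h <- dm[1, 2] / 2
    sprintf("(%s:%s,%s:%s);", frag[1], nwk_num(h), frag[2], nwk_num(h))
  } else {
    a <- max((dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2, 0)
    b <- max((dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2, 0)
    c3 <- max((dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2, 0)
    sprintf("(%s:%s,%s:%s,%s:%s);",
            frag[1], nwk_num(a), frag[2], nwk_num(b), frag[3], nwk_num(c3))
  }
  read_newick(nwk)
}

#' Alignment-free phylogeny from genome sequences
#'
#' The full feature-frequency-profile pipeline: count k-mers, normalize
#' each genome's counts to a frequency profile, compute the pairwise
#' Jensen-Shannon distance matrix, and build a neighbor-joining tree.
#'
#' @param genomes Genome tibble from [read_fasta()] (>= 3 genomes for a
#'   resolved tree).
#' @param k Optional k override; by default chosen by [choose_k()].
#' @param canonical Count canonical (strand-collapsed) k-mers.
#' @return A list with elements `k`, `distances` (labeled matrix) and
#'   `tree` ([ape::phylo]).
#' @export
ffp_phylogeny <- function(genomes, k = NULL, canonical = FALSE) {
  assert_genomes(genomes)
  k <- choose_k(genomes, override = k)
  freqs <- kmer_frequencies(genomes, k = k, canonical = canonical)
  d <- jsd_matrix(freqs)
  list(k = k, distances = d, tree = neighbor_joining(d))
}
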