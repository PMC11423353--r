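dna_bases <- c("A", "C", "G", "T")

#' Default lifestyle marker-motif catalog
#'
#' Five 12-residue amino-acid motifs standing in for temperate-specific
#' domains (integrase/excisionase-like markers) in simulated datasets, and
#' an empty lytic list: lytic genomes carry no marker. Purely synthetic
#' sequences, chosen to be effectively impossible to hit by chance in
#' random background DNA.
#'
#' @return Named list with character vectors `temperate` and `lytic`.
#' @export
default_motif_catalog <- function() {
  list(
    temperate = c(
      int_marker_1 = "WQHKDERYFNML",
      int_marker_2 = "CPAGVTSIWYHK",
      int_marker_3 = "MLFYREKDHQNW",
      int_marker_4 = "GAVLIPFMWSTC",
      int_marker_5 = "HKRDENQYWFMI"
    ),
    lytic = character(0)
  )
}

random_genome <- function(length) {
  paste(sample(dna_bases, length, replace = TRUE), collapse = "")
}

#' Random phylogeny scaled to a maximum path substitution probability
#'
#' Draws a random topology with edge lengths uniform on
#' `[min_rel, 1]`, then rescales all edges so the deepest root-to-tip
#' path has substitution probability `max_path`. Keeping every edge at
#' least `min_rel` of the longest keeps all internal branches
#' informative (hundreds of substitutions at typical genome lengths)
#' while the path bound keeps k-mer profiles far from saturation —
#' the regime in which distance-based reconstruction is expected to
#' succeed.
#'
#' @param ntips Number of tips.
#' @param max_path Maximum root-to-tip substitution probability
#'   (default 0.2).
#' @param min_rel Lower bound of the uniform edge-length draw relative
#'   to the upper bound (default 0.3).
#' @param seed Optional integer seed.
#' @return A rooted [ape::phylo] tree whose branch lengths are per-site
#'   substitution probabilities.
#' @export
sim_phage_tree <- function(ntips = 12L, max_path = 0.2, min_rel = 0.3,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (max_path <= 0 || max_path >= 0.75) {
    stop_parameter("max_path must lie in (0, 0.75)")
  }
  tree <- ape::rtree(ntips)
  tree$edge.length <- stats::runif(length(tree$edge.length), min_rel, 1)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth * max_path
  tree
}

#' Evolve genomes along a known tree
#'
#' Draws a root sequence uniformly over A/C/G/T and walks the tree from
#' the root: along each branch every site independently substitutes to a
#' uniformly chosen different base with probability equal to the branch
#' length (a Jukes-Cantor-style process, no indels). Branch lengths are
#' therefore per-site substitution probabilities and must be below 0.75
#' (saturation).
#'
#' @param tree An [ape::phylo] tree with named tips and branch lengths in
#'   `[0, 0.75)`.
#' @param genome_length Root genome length in nt.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return List with `genomes` (tibble `id`, `description`, `sequence`,
#'   `length`, one row per tip) and `tree` (the generating tree).
#' @export
evolve_genomes <- function(tree, genome_length = 20000L, seed = 1L) {
  if (!inherits(tree, "phylo")) stop_parameter("`tree` must be a phylo object")
  if (is.null(tree$edge.length)) stop_parameter("tree must have branch lengths")
  if (any(tree$edge.length < 0) || any(tree$edge.length >= 0.75)) {
    stop_parameter("branch substitution probabilities must lie in [0, 0.75)")
  }
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  n_nodes <- ntip + tree$Nnode
  seqs <- vector("list", n_nodes)
  seqs[[root]] <- sample(dna_bases, genome_length, replace = TRUE)
  tree_pre <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(tree_pre$edge))) {
    parent <- tree_pre$edge[e, 1L]
    child <- tree_pre$edge[e, 2L]
    p <- tree_pre$edge.length[e]
    s <- seqs[[parent]]
    hit <- which(stats::runif(genome_length) < p)
    if (length(hit)) {
      # uniform choice among the three alternative bases, vectorized as a
      # random nonzero shift in base index mod 4
      idx <- match(s[hit], dna_bases) - 1L
      shift <- sample(3L, length(hit), replace = TRUE)
      s[hit] <- dna_bases[((idx + shift) %% 4L) + 1L]
    }
    seqs[[child]] <- s
  }
  genomes <- tibble(
    id = tree$tip.label,
    description = tree$tip.label,
    sequence = vapply(seqs[seq_len(ntip)], paste, character(1), collapse = ""),
    length = genome_length
  )
  list(genomes = genomes, tree = tree)
}

# Fixed codon per amino acid (reverse translation; determinism over realism).
.codon_of <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)

reverse_translate <- function(aa) {
  codons <- .codon_of[strsplit(aa, "", fixed = TRUE)[[1L]]]
  if (anyNA(codons)) stop_parameter(sprintf("motif has non-standard residue: %s", aa))
  paste(codons, collapse = "")
}

#' Simulate lifestyle-labeled genomes with implanted domain motifs
#'
#' Generates random background genomes for two classes. For each genome
#' of class `c`, each marker motif of that class is (with the class's
#' implant rate) reverse-translated with a fixed codon table and inserted
#' in reading frame +1 inside a guaranteed stop-free window of at least
#' 40 codons, flanked by stop codons, so a positive scan of the motif is
#' guaranteed and an unimplanted motif cannot occur by chance.
#'
#' @param n_per_class Genomes per class.
#' @param motifs Motif catalog as from [default_motif_catalog()]; the
#'   temperate markers are implanted at `implant_rates["temperate"]` into
#'   temperate genomes and at `implant_rates["lytic"]` into lytic ones.
#' @param implant_rates Named per-class per-motif implant probabilities in
#'   `[0, 1]` (default: temperate 1, lytic 0 — perfectly separable).
#' @param genome_length Background genome length (must fit all windows).
#' @param seed Integer seed.
#' @return List with `genomes` (tibble), `labels` (tibble `id`,
#'   `lifestyle`) and `domains` (the corresponding motif `domain_set`).
#' @export
implant_domains <- function(n_per_class = 100L,
                            motifs = default_motif_catalog(),
                            implant_rates = c(temperate = 1, lytic = 0),
                            genome_length = 3000L, seed = 1L) {
  markers <- motifs$temperate
  if (!length(markers)) stop_parameter("motif catalog has no temperate markers")
  if (any(implant_rates < 0 | implant_rates > 1)) {
    stop_parameter("implant rates must lie in [0, 1]")
  }
  pad <- 20L  # stop-free padding codons on each side of the motif
  win_nt <- vapply(markers, function(m) 3L * (2L * pad + nchar(m)) + 6L, integer(1))
  slot0 <- cumsum(c(1L, win_nt + 30L))  # fixed, non-overlapping slots
  if (slot0[length(markers)] + win_nt[length(markers)] > genome_length) {
    stop_parameter("genome_length too short to host the marker windows")
  }
  set.seed(seed)
  make_class <- function(class, n) {
    rate <- implant_rates[[class]]
    purrr::map_chr(seq_len(n), function(i) {
      g <- random_genome(genome_length)
      for (mi in seq_along(markers)) {
        if (stats::runif(1) < rate) {
          core <- paste0(
            strrep(.codon_of[["A"]], pad),
            reverse_translate(markers[[mi]]),
            strrep(.codon_of[["A"]], pad)
          )
          insert <- paste0("TAA", core, "TAA")
          at <- slot0[mi]
          at <- at - (at - 1L) %% 3L  # keep frame +1
          g <- paste0(substr(g, 1L, at - 1L), insert,
                      substr(g, at + nchar(insert), genome_length))
        }
      }
      g
    })
  }
  seq_t <- make_class("temperate", n_per_class)
  seq_l <- make_class("lytic", n_per_class)
  ids <- c(sprintf("temperate_%03d", seq_len(n_per_class)),
           sprintf("lytic_%03d", seq_len(n_per_class)))
  genomes <- tibble(
    id = ids, description = ids,
    sequence = c(seq_t, seq_l),
    length = nchar(c(seq_t, seq_l))
  )
  labels <- tibble(id = ids,
                   lifestyle = rep(c("temperate", "lytic"), each = n_per_class))
  list(genomes = genomes, labels = labels,
       domains = motif_domain_set(markers, provenance = "simulated marker motifs"))
}

#' Write a synthetic annotation triplet with known overlap structure
#'
#' Lays out non-overlapping CDS features on one contig and writes them in
#' the three pipeline dialects (Pharokka GFF3, PHASTER detail text, RAST
#' TSV) so that exactly the designed numbers of coordinate-identical
#' common features, per-tool-unique features, and pairwise-shared
#' features are present. The returned truth counts are the oracle for
#' [compare_annotations()].
#'
#' @param dir Output directory (created if needed).
#' @param design Named list/vector of counts: `common`, `pharokka_only`,
#'   `phaster_only`, `rast_only`, and optional pairwise counts
#'   `pharokka_phaster`, `pharokka_rast`, `phaster_rast`.
#' @param genome_length Contig length the features must fit into.
#' @param seed Integer seed (feature lengths, strands, products).
#' @return List with `paths` (named: `pharokka`, `phaster`, `rast`),
#'   `truth` (the design counts, zero-filled) and `features` (the laid-out
#'   feature tibble with a `membership` column).
#' @export
make_annotation_triplet <- function(dir, design = list(common = 6, pharokka_only = 2),
                                    genome_length = 60000L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- c("common", "pharokka_only", "phaster_only", "rast_only",
            "pharokka_phaster", "pharokka_rast", "phaster_rast")
  counts <- stats::setNames(integer(length(keys)), keys)
  design <- unlist(design)
  unknown <- setdiff(names(design), keys)
  if (length(unknown)) {
    stop_parameter(sprintf("unknown design key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (any(design < 0)) stop_parameter("design counts must be non-negative")
  counts[names(design)] <- as.integer(design)
  membership <- rep(
    c(list(c("pharokka", "phaster", "rast")),
      list("pharokka"), list("phaster"), list("rast"),
      list(c("pharokka", "phaster")), list(c("pharokka", "rast")),
      list(c("phaster", "rast"))),
    counts
  )
  n <- length(membership)
  if (n == 0L) stop_parameter("design places no features")
  set.seed(seed)
  len <- 3L * sample(60:200, n, replace = TRUE)
  gap <- 50L
  start <- cumsum(c(101L, utils::head(len, -1L) + gap))
  if (start[n] + len[n] - 1L > genome_length) {
    stop_parameter("features do not fit in genome_length; increase it or reduce counts")
  }
  feats <- tibble(
    feature = sprintf("feat_%03d", seq_len(n)),
    start = start,
    end = start + len - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    product = sprintf("protein %03d", seq_len(n)),
    membership = membership
  )
  in_tool <- function(tool) {
    vapply(feats$membership, function(m) tool %in% m, logical(1))
  }

  gff_path <- file.path(dir, "pharokka.gff")
  ph <- feats[in_tool("pharokka"), ]
  writeLines(c(
    "##gff-version 3",
    sprintf("contig1\tPharokka\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s",
            ph$start, ph$end, ph$strand, ph$feature, ph$product)
  ), gff_path)

  txt_path <- file.path(dir, "phaster.txt")
  pt <- feats[in_tool("phaster"), ]
  coord <- ifelse(pt$strand == "-",
                  sprintf("complement(%d..%d)", pt$start, pt$end),
                  sprintf("%d..%d", pt$start, pt$end))
  writeLines(c(
    "# region details",
    "CDS_POSITION   BLAST_HIT",
    sprintf("%s   %s", coord, pt$product)
  ), txt_path)

  rast_path <- file.path(dir, "rast.tsv")
  rt <- feats[in_tool("rast"), ]
  rast_start <- ifelse(rt$strand == "-", rt$end, rt$start)
  rast_stop <- ifelse(rt$strand == "-", rt$start, rt$end)
  writeLines(c(
    paste("contig_id", "type", "start", "stop", "strand", "function", sep = "\t"),
    sprintf("contig1\tCDS\t%d\t%d\t%s\t%s",
            rast_start, rast_stop, rt$strand, rt$product)
  ), rast_path)

  list(
    paths = c(pharokka = gff_path, phaster = txt_path, rast = rast_path),
    truth = counts,
    features = feats
  )
}
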