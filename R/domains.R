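#' Build a domain set from exact amino-acid motifs
#'
#' The motif backend treats each domain as an exact amino-acid substring;
#' a fragment matches when the motif occurs verbatim. This backend is
#' hermetic (no external scanner) and satisfies the same presence/absence
#' contract as the profile-HMM backend.
#'
#' @param motifs Named character vector: domain name -> amino-acid motif.
#' @param provenance Free-text note recorded with the set.
#' @return A `domain_set`: tibble with columns `name`, `kind`, `spec`,
#'   fixed row order (feature vectors index into it), plus `provenance`
#'   and `fingerprint` attributes.
#' @export
motif_domain_set <- function(motifs, provenance = "exact-motif test backend") {
  if (length(motifs) == 0L) stop_parameter("motif set must be non-empty")
  if (is.null(names(motifs)) || any(!nzchar(names(motifs)))) {
    stop_parameter("motifs must be a named character vector")
  }
  new_domain_set(tibble(name = names(motifs), kind = "motif",
                        spec = unname(motifs)), provenance)
}

#' Build a domain set from profile-HMM files
#'
#' Each file must hold one HMMER3 profile; scanning shells out to
#' `hmmsearch`. Domain names default to the file base names.
#'
#' @param paths Character vector of `.hmm` file paths.
#' @param names Optional domain names (default: file base names).
#' @param provenance Free-text note recorded with the set.
#' @return A `domain_set` (see [motif_domain_set()]).
#' @export
hmm_domain_set <- function(paths, names = NULL,
                           provenance = "profile-HMM collection") {
  if (length(paths) == 0L) stop_parameter("domain set must be non-empty")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_parameter(sprintf("HMM file(s) not found: %s", paste(missing, collapse = ", ")))
  }
  nm <- names %||% tools::file_path_sans_ext(basename(paths))
  new_domain_set(tibble(name = nm, kind = "profile_hmm", spec = paths), provenance)
}

new_domain_set <- function(tbl, provenance) {
  if (anyDuplicated(tbl$name)) {
    stop_validation(sprintf("duplicate domain name(s): %s",
                            paste(unique(tbl$name[duplicated(tbl$name)]), collapse = ", ")))
  }
  attr(tbl, "provenance") <- provenance
  attr(tbl, "fingerprint") <- domain_fingerprint(tbl)
  class(tbl) <- c("domain_set", class(tbl))
  tbl
}

# md5 over the ordered (name, kind, spec-content) triples; for HMM files
# the file content is hashed so a renamed copy keeps its identity
domain_fingerprint <- function(domains) {
  spec_id <- ifelse(domains$kind == "profile_hmm",
                    unname(tools::md5sum(domains$spec)), domains$spec)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(domains$name, domains$kind, spec_id, sep = "\t"), tmp)
  unname(tools::md5sum(tmp))
}

#' Scan one genome's protein fragments for domain presence
#'
#' Produces the binary presence/absence feature vector over a fixed,
#' ordered domain set: bit `d` is 1 iff any fragment matches domain `d`.
#' Motif domains match by exact substring; profile-HMM domains match when
#' `hmmsearch` reports a full-sequence E-value at or below
#' `evalue_cutoff`.
#'
#' @param fragments Fragment tibble from [six_frame_translate()]; all rows
#'   must come from a single genome. An empty tibble gives an all-zero
#'   vector.
#' @param domains A `domain_set`.
#' @param evalue_cutoff E-value threshold for profile-HMM hits.
#' @return Named integer vector of 0/1 bits, ordered as `domains`.
#' @export
scan_domains <- function(fragments, domains, evalue_cutoff = 1e-5) {
  if (!inherits(domains, "domain_set")) stop_parameter("`domains` must be a domain_set")
  if (nrow(fragments) > 0L && length(unique(fragments$genome_id)) > 1L) {
    stop_validation("fragments come from more than one genome")
  }
  bits <- stats::setNames(integer(nrow(domains)), domains$name)
  if (nrow(fragments) == 0L) return(bits)
  is_motif <- domains$kind == "motif"
  if (any(is_motif)) {
    bits[is_motif] <- vapply(domains$spec[is_motif], function(p) {
      as.integer(any(grepl(p, fragments$aa_seq, fixed = TRUE)))
    }, integer(1))
  }
  if (any(!is_motif)) {
    hits <- hmmsearch_hits(fragments$aa_seq, domains$spec[!is_motif], evalue_cutoff)
    bits[!is_motif] <- hits
  }
  bits
}

hmmsearch_hits <- function(aa_seqs, hmm_paths, evalue_cutoff) {
  if (Sys.which("hmmsearch") == "") {
    abort("hmmsearch (HMMER) not found on PATH; profile-HMM scanning unavailable",
          class = "phagetools_backend_error")
  }
  faa <- tempfile(fileext = ".faa")
  on.exit(unlink(faa))
  writeLines(paste0(">frag", seq_along(aa_seqs), "\n", aa_seqs), faa)
  vapply(hmm_paths, function(hmm) {
    tbl <- tempfile(fileext = ".tbl")
    on.exit(unlink(tbl), add = TRUE)
    status <- system2("hmmsearch",
                      c("--tblout", tbl, "-E", format(evalue_cutoff, scientific = TRUE),
                        "--noali", shQuote(hmm), shQuote(faa)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L) {
      abort(sprintf("hmmsearch failed (exit %d) for %s", status, hmm),
            class = "phagetools_backend_error")
    }
    lines <- readLines(tbl, warn = FALSE)
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines)) return(0L)
    ev <- suppressWarnings(as.numeric(vapply(strsplit(trimws(lines), "[ \t]+"),
                                             `[`, character(1), 5L)))
    as.integer(any(!is.na(ev) & ev <= evalue_cutoff))
  }, integer(1))
}

#' Presence/absence feature matrix for a genome collection
#'
#' Runs [six_frame_translate()] then [scan_domains()] per genome. A genome
#' with no fragments of the minimum length gets an all-zero row.
#'
#' @param genomes Genome tibble with unique ids.
#' @param domains A `domain_set`.
#' @param min_aa Minimum fragment length (default 40).
#' @param evalue_cutoff E-value threshold for profile-HMM domains.
#' @return Binary integer matrix, rows = genome ids, columns = domain
#'   names, with the domain-set fingerprint as attribute `fingerprint`.
#' @export
build_feature_matrix <- function(genomes, domains, min_aa = 40L,
                                 evalue_cutoff = 1e-5) {
  assert_genomes(genomes)
  frags <- six_frame_translate(genomes, min_aa = min_aa)
  rows <- lapply(genomes$id, function(id) {
    tryCatch(
      scan_domains(frags[frags$genome_id == id, , drop = FALSE], domains,
                   evalue_cutoff = evalue_cutoff),
      phagetools_error = function(e) {
        abort(sprintf("genome %s: %s", id, conditionMessage(e)),
              class = class(e), parent = e)
      }
    )
  })
  m <- do.call(rbind, rows)
  rownames(m) <- genomes$id
  attr(m, "fingerprint") <- attr(domains, "fingerprint")
  m
}
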