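comparison_modes <- c("common_annotation", "pharokka_only", "phaster_only",
                      "rast_only", "all")

bind_annotation_sets <- function(sets) {
  if (inherits(sets, "annotation_set")) sets <- list(sets)
  if (length(sets) < 2L || length(sets) > 3L) {
    stop_parameter("provide 2 or 3 annotation sets")
  }
  sources <- vapply(sets, function(s) s$source[1L], character(1))
  if (anyDuplicated(sources)) stop_parameter("annotation sets must come from distinct tools")
  # each set is single-contig by construction; tools name the contig
  # differently (PHASTER exports none), so names are not compared across sets
  dplyr::bind_rows(lapply(sets, as_tibble))
}

#' Group annotations from multiple pipelines into matched features
#'
#' With `tolerance_bp = 0` records are grouped by exact
#' `(start, end, strand)` identity — an equivalence relation. With a
#' positive tolerance, same-strand records whose starts and ends each
#' differ by at most `tolerance_bp` are linked, and groups are the
#' connected components (single linkage; non-transitive boundaries merge
#' by chaining). Every record lands in exactly one group.
#'
#' @param sets List of 2-3 `annotation_set` tibbles on the same contig.
#' @param tolerance_bp Coordinate slack in base pairs (default 0, exact).
#' @return Tibble of all input records with additional columns `group`
#'   (integer id) and `n_sources` (number of distinct tools in the
#'   record's group); attribute `sources` lists the input tools.
#' @export
match_annotations <- function(sets, tolerance_bp = 0L) {
  recs <- bind_annotation_sets(sets)
  if (tolerance_bp < 0L) stop_parameter("tolerance_bp must be >= 0")
  n <- nrow(recs)
  if (tolerance_bp == 0L) {
    key <- paste(recs$start, recs$end, recs$strand)
    grp <- match(key, unique(key))
  } else {
    pairs <- list()
    ord <- order(recs$start)
    for (a in seq_len(n - 1L)) {
      i <- ord[a]
      for (b in seq.int(a + 1L, n)) {
        j <- ord[b]
        if (recs$start[j] - recs$start[i] > tolerance_bp) break
        if (recs$strand[i] == recs$strand[j] &&
            abs(recs$end[i] - recs$end[j]) <= tolerance_bp) {
          pairs[[length(pairs) + 1L]] <- c(i, j)
        }
      }
    }
    g <- igraph::graph_from_edgelist(
      if (length(pairs)) do.call(rbind, pairs) else matrix(integer(), ncol = 2),
      directed = FALSE
    )
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    grp <- match(comp, unique(comp))
  }
  recs$group <- grp
  recs <- recs %>%
    dplyr::group_by(.data$group) %>%
    dplyr::mutate(n_sources = dplyr::n_distinct(.data$source)) %>%
    dplyr::ungroup()
  attr(recs, "sources") <- unique(recs$source)
  recs
}

#' Compare annotations across pipelines
#'
#' Builds the comparison table for the requested mode:
#' \describe{
#'   \item{common_annotation}{groups containing at least one record from
#'     every input tool.}
#'   \item{<tool>_only}{singleton groups whose sole record comes from that
#'     tool.}
#'   \item{all}{every group.}
#' }
#' Rows carry one product and one `start..end(strand)` coordinate column
#' per tool (blank where a tool lacks the feature) and are sorted by the
#' requested key: `location` = start ascending, `length` = feature length
#' descending (ties by start), `product` = first product alphabetically.
#'
#' @param sets List of 2-3 `annotation_set` tibbles.
#' @param mode One of `common_annotation`, `pharokka_only`, `phaster_only`,
#'   `rast_only`, `all`.
#' @param sort_by One of `location`, `length`, `product`.
#' @param tolerance_bp Passed to [match_annotations()].
#' @return An `annotation_comparison`: list with `mode`, `rows` (the
#'   comparison tibble), `counts` (named totals: per-tool record counts,
#'   `common`, each `<tool>_only`, `partial`) and `matched` (the full
#'   grouped record table).
#' @export
compare_annotations <- function(sets, mode = "common_annotation",
                                sort_by = "location", tolerance_bp = 0L) {
  if (!mode %in% comparison_modes) {
    stop_parameter(sprintf("unknown mode `%s`; valid modes: %s",
                           mode, paste(comparison_modes, collapse = ", ")))
  }
  if (!sort_by %in% c("location", "length", "product")) {
    stop_parameter("sort_by must be one of location, length, product")
  }
  matched <- match_annotations(sets, tolerance_bp = tolerance_bp)
  sources <- attr(matched, "sources")
  if (grepl("_only$", mode)) {
    tool <- sub("_only$", "", mode)
    if (!tool %in% sources) {
      stop_parameter(sprintf("mode `%s` requires a %s annotation set among the inputs",
                             mode, tool))
    }
  }
  n_tools <- length(sources)

  groups <- matched %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      n_sources = .data$n_sources[1L],
      n_records = dplyr::n(),
      start = min(.data$start),
      length = max(.data$end - .data$start + 1L),
      product = sort(.data$product)[1L],
      .groups = "drop"
    )
  category <- function(g) {
    if (g$n_sources == n_tools) "common"
    else if (g$n_records == 1L) "only"
    else "partial"
  }
  groups$category <- vapply(seq_len(nrow(groups)),
                            function(i) category(groups[i, ]), character(1))
  only_tool <- matched %>%
    dplyr::filter(.data$group %in% groups$group[groups$category == "only"]) %>%
    dplyr::distinct(.data$group, .data$source)

  counts <- c(
    stats::setNames(
      vapply(sources, function(s) sum(matched$source == s), integer(1)),
      paste0("total_", sources)
    ),
    common = sum(groups$category == "common"),
    stats::setNames(
      vapply(sources, function(s) sum(only_tool$source == s), integer(1)),
      paste0(sources, "_only")
    ),
    partial = sum(groups$category == "partial")
  )

  keep <- switch(mode,
    common_annotation = groups$group[groups$category == "common"],
    all = groups$group,
    {
      tool <- sub("_only$", "", mode)
      only_tool$group[only_tool$source == tool]
    }
  )
  sel <- groups[groups$group %in% keep, ]
  sel <- switch(sort_by,
    location = sel[order(sel$start), ],
    length = sel[order(-sel$length, sel$start), ],
    product = sel[order(sel$product, sel$start), ]
  )

  wide <- matched %>%
    dplyr::mutate(
      coords = sprintf("%d..%d(%s)", .data$start, .data$end, .data$strand)
    ) %>%
    dplyr::group_by(.data$group, .data$source) %>%
    dplyr::summarise(
      product = paste(.data$product, collapse = "; "),
      coords = paste(.data$coords, collapse = "; "),
      nt_seq = paste(stats::na.omit(.data$nt_seq), collapse = "; "),
      aa_seq = paste(stats::na.omit(.data$aa_seq), collapse = "; "),
      .groups = "drop"
    ) %>%
    tidyr::pivot_wider(
      id_cols = "group",
      names_from = "source",
      values_from = c("product", "coords", "nt_seq", "aa_seq"),
      values_fill = ""
    )
  has_seq <- any(!is.na(matched$nt_seq)) || any(!is.na(matched$aa_seq))
  if (!has_seq) wide <- dplyr::select(wide, -dplyr::starts_with(c("nt_seq", "aa_seq")))
  rows <- dplyr::left_join(
    dplyr::select(sel, "group", "start", "length"), wide, by = "group"
  )
  structure(
    list(mode = mode, sort_by = sort_by, rows = rows, counts = counts,
         matched = matched, sources = sources),
    class = "annotation_comparison"
  )
}

#' @export
print.annotation_comparison <- function(x, ...) {
  cat(sprintf("Annotation comparison (%s, sorted by %s): %d row(s)\n",
              x$mode, x$sort_by, nrow(x$rows)))
  cat("Counts:\n")
  for (nm in names(x$counts)) cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Per-category counts of an annotation comparison
#' @param x An `annotation_comparison`.
#' @param ... Unused.
#' @return One-row tibble of the count summary.
#' @export
glance.annotation_comparison <- function(x, ...) {
  as_tibble(as.list(x$counts))
}

#' Bar chart of annotation-comparison category counts
#' @param object An `annotation_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.annotation_comparison <- function(object, ...) {
  keep <- grep("^total_", names(object$counts), invert = TRUE, value = TRUE)
  df <- tibble(category = factor(keep, levels = keep),
               count = as.integer(object$counts[keep]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$count)) +
    ggplot2::geom_col(fill = "#1f77b4") +
    ggplot2::labs(x = NULL, y = "features") +
    ggplot2::theme_minimal()
}

#' Export a comparison table to CSV or TSV
#'
#' Writes a header plus one row per matched group; per-tool product and
#' coordinate columns are blank where a tool lacks the feature, and
#' nucleotide/amino-acid sequence columns are included when any record
#' carries them. An empty result yields a header-only file.
#'
#' @param result An `annotation_comparison`.
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_comparison <- function(result, path, format = "csv") {
  if (!inherits(result, "annotation_comparison")) {
    stop_parameter("`result` must be an annotation_comparison")
  }
  if (!format %in% c("csv", "tsv")) {
    stop_parameter(sprintf("unsupported format `%s`; use csv or tsv", format))
  }
  if (format == "csv") readr::write_csv(result$rows, path)
  else readr::write_tsv(result$rows, path)
  invisible(path)
}
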